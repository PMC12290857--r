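#' Resample a volumetric map onto a target grid
#'
#' Trilinear (default) or nearest-neighbour interpolation of a map (e.g. a
#' 3 mm PET receptor-density volume) onto a target grid (e.g. 2 mm
#' isotropic). Trilinear output values are bounded by the input extremes.
#'
#' @param map a `stat_map` (or list with `data` and `grid`).
#' @param target_grid the [volume_grid()] to resample onto.
#' @param method `"trilinear"` for continuous maps, `"nearest"` for label
#'   maps.
#' @return A `stat_map` of kind `"density"` on `target_grid`.
#' @export
resample_map <- function(map, target_grid,
                         method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  src <- map$grid
  arr <- map$data
  vox <- mm_to_vox(src, grid_coords(target_grid, masked = FALSE))
  inside <- vox[, 1] >= 1 & vox[, 1] <= src$shape[1] &
    vox[, 2] >= 1 & vox[, 2] <= src$shape[2] &
    vox[, 3] >= 1 & vox[, 3] <= src$shape[3]
  if (!any(inside & c(target_grid$mask))) {
    stop("fields of view do not overlap")
  }
  out <- numeric(nrow(vox))
  v <- vox[inside, , drop = FALSE]
  if (method == "nearest") {
    ijk <- pmin(pmax(round(v), 1), matrix(src$shape, nrow(v), 3, TRUE))
    out[inside] <- arr[ijk_to_linear(src$shape, ijk)]
  } else {
    i0 <- pmin(pmax(floor(v), 1), matrix(src$shape - 1L, nrow(v), 3, TRUE))
    fr <- v - i0
    fr <- pmin(pmax(fr, 0), 1)
    acc <- numeric(nrow(v))
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) fr[, 1] else 1 - fr[, 1]) *
        (if (dj) fr[, 2] else 1 - fr[, 2]) *
        (if (dk) fr[, 3] else 1 - fr[, 3])
      corner <- cbind(i0[, 1] + di, i0[, 2] + dj, i0[, 3] + dk)
      acc <- acc + w * arr[ijk_to_linear(src$shape, corner)]
    }
    out[inside] <- acc
  }
  stat_map(target_grid, array(out, target_grid$shape), "density")
}

#' Rescale a map to the 0-100 range
#'
#' Linear rescaling of the in-mask values so their minimum is 0 and maximum
#' is 100 (the convention for the PET-derived receptor density maps this
#' pipeline consumes). Idempotent; a constant map is an error. The original
#' extremes are recorded in attributes `orig_min` / `orig_max`.
#'
#' @param map a `stat_map`.
#' @return the rescaled `stat_map` of kind `"density"`.
#' @export
rescale_map <- function(map) {
  g <- map$grid
  v <- map$data[g$mask]
  lo <- min(v)
  hi <- max(v)
  if (hi - lo < .Machine$double.eps) stop("cannot rescale a constant map")
  arr <- map$data
  arr[g$mask] <- (v - lo) / (hi - lo) * 100
  arr[!g$mask] <- 0
  out <- stat_map(g, arr, "density")
  attr(out, "orig_min") <- lo
  attr(out, "orig_max") <- hi
  out
}

#' Node-wise density profile
#'
#' Mean map value within a sphere around each node, over grey-matter voxels.
#' Following the sampling convention for annotation maps, the default sphere
#' is 5 mm in *diameter* (radius 2.5 mm) -- note this differs from the 5 mm
#' *radius* used for BOLD sphere time series.
#'
#' @param map a `stat_map`.
#' @param nodes a [node_set()].
#' @param gm_mask optional grey-matter mask (defaults to the grid mask).
#' @param radius_mm sampling-sphere radius, mm (default 2.5).
#' @return named numeric vector, one mean density per node (node order
#'   preserved).
#' @export
sample_node_density <- function(map, nodes, gm_mask = NULL, radius_mm = 2.5) {
  g <- map$grid
  if (is.null(gm_mask)) gm_mask <- g$mask
  xyz <- node_coords(nodes)
  out <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    vox <- sphere_voxels(g, xyz[i, ], radius_mm, gm_mask)
    if (!length(vox)) {
      stop(sprintf("node '%s' has an empty sampling sphere (radius %g mm)",
                   nodes$region[i], radius_mm))
    }
    out[i] <- mean(map$data[vox])
  }
  names(out) <- nodes$region
  out
}

#' Two-dataset effect-size screen
#'
#' Spearman rank correlation between a node-level graph metric (one vector
#' per dataset, e.g. discovery and replication) and each annotation map's
#' node density profile. A map passes iff |rho| exceeds `threshold` in *both*
#' datasets with matching sign.
#'
#' @param metric_discovery,metric_replication per-node metric vectors with
#'   the same node order as the profiles.
#' @param profiles named list (or nodes x maps matrix) of node density
#'   profiles, one per annotation map.
#' @param threshold absolute-rho screen threshold (default 0.3).
#' @return data.frame: map, rho_discovery, rho_replication, pass.
#' @export
screen_correlations <- function(metric_discovery, metric_replication,
                                profiles, threshold = 0.3) {
  if (is.matrix(profiles)) {
    profiles <- stats::setNames(
      lapply(seq_len(ncol(profiles)), function(j) profiles[, j]),
      colnames(profiles) %||% paste0("map_", seq_len(ncol(profiles))))
  }
  rho <- function(metric, prof) {
    if (stats::sd(metric) == 0 || stats::sd(prof) == 0) {
      warning("constant vector in screen: correlation undefined, map fails")
      return(NA_real_)
    }
    stats::cor(metric, prof, method = "spearman")
  }
  rows <- lapply(names(profiles), function(nm) {
    r1 <- rho(metric_discovery, profiles[[nm]])
    r2 <- rho(metric_replication, profiles[[nm]])
    pass <- !is.na(r1) && !is.na(r2) && abs(r1) > threshold &&
      abs(r2) > threshold && sign(r1) == sign(r2)
    data.frame(map = nm, rho_discovery = r1, rho_replication = r2,
               pass = pass)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pairwise_distances <- function(xyz) {
  as.numeric(stats::dist(xyz))
}

#' Distance-constrained random-network null
#'
#' Rejection-samples `n_networks` random node sets of the same size as the
#' empirical network from grey-matter voxel centres, accepting a candidate
#' iff its minimum, mean and maximum pairwise Euclidean distances each lie
#' within one standard deviation (the SD of the empirical network's pairwise
#' distance distribution, by default) of the empirical minimum, mean and
#' maximum. For each accepted network the Spearman correlation between the
#' supplied node metric and that network's density profile on `map` forms
#' the null distribution.
#'
#' @param empirical_nodes the observed [node_set()].
#' @param grid the map's [volume_grid()].
#' @param gm_mask conservative grey-matter mask to sample from (defaults to
#'   the grid mask).
#' @param map annotation `stat_map` to sample.
#' @param metric per-node metric vector (empirical node order).
#' @param n_networks ensemble size (default 1000).
#' @param seed RNG seed.
#' @param radius_mm sampling-sphere radius (default 2.5).
#' @param sd_band constraint half-width in mm; default `NULL` uses the SD of
#'   the empirical pairwise-distance distribution.
#' @param max_attempts abort (with a diagnostic of which constraint binds)
#'   once the acceptance rate over at least this many attempts falls below
#'   1e-4.
#' @return A `null_ensemble`: list with `networks` (list of coordinate
#'   matrices), `sphere_vox` (cached per-network sphere indices), `null_rho`,
#'   `constraints` (empirical min/mean/max and band) and `acceptance_rate`.
#' @export
random_network_null <- function(empirical_nodes, grid, gm_mask = NULL, map,
                                metric, n_networks = 1000, seed = 1,
                                radius_mm = 2.5, sd_band = NULL,
                                max_attempts = 2e7) {
  if (is.null(gm_mask)) gm_mask <- grid$mask
  xyz_e <- node_coords(empirical_nodes)
  n_nodes <- nrow(xyz_e)
  d_e <- pairwise_distances(xyz_e)
  ref <- c(min = min(d_e), mean = mean(d_e), max = max(d_e))
  band <- sd_band %||% stats::sd(d_e)
  gm_idx <- which(gm_mask & grid$mask)
  gm_xyz <- vox_to_mm(grid, arrayInd(gm_idx, grid$shape))
  set.seed(seed)
  networks <- vector("list", n_networks)
  fails <- c(min = 0, mean = 0, max = 0)
  accepted <- 0L
  attempts <- 0L
  while (accepted < n_networks) {
    attempts <- attempts + 1L
    if (attempts > 1e4 && accepted / attempts < 1e-4 ||
        attempts > max_attempts) {
      stop("rejection sampling acceptance rate below 1e-4; ",
           "binding constraint rejections so far: ",
           paste(names(fails), round(fails / attempts, 3), collapse = ", "))
    }
    cand <- gm_xyz[sample.int(length(gm_idx), n_nodes), , drop = FALSE]
    d <- pairwise_distances(cand)
    ok_min <- abs(min(d) - ref["min"]) <= band
    ok_mean <- abs(mean(d) - ref["mean"]) <= band
    ok_max <- abs(max(d) - ref["max"]) <= band
    if (!ok_min) fails["min"] <- fails["min"] + 1
    if (!ok_mean) fails["mean"] <- fails["mean"] + 1
    if (!ok_max) fails["max"] <- fails["max"] + 1
    if (ok_min && ok_mean && ok_max) {
      accepted <- accepted + 1L
      networks[[accepted]] <- cand
    }
  }
  sphere_vox <- lapply(networks, function(xyz) {
    lapply(seq_len(n_nodes), function(i) {
      sphere_voxels(grid, xyz[i, ], radius_mm, gm_mask)
    })
  })
  ens <- structure(list(networks = networks, sphere_vox = sphere_vox,
                        grid = grid, gm_mask = gm_mask,
                        radius_mm = radius_mm,
                        constraints = list(reference = ref, band = band,
                                           empirical_sd = stats::sd(d_e)),
                        acceptance_rate = accepted / attempts,
                        metric = metric),
                   class = "null_ensemble")
  ens$null_rho <- ensemble_null_rho(ens, map, metric)
  ens
}

#' Null correlation distribution of an ensemble on a map
#'
#' Recomputes the Spearman null distribution of an existing
#' [random_network_null()] ensemble against another annotation map (the
#' random node sets and their cached sampling spheres are reused).
#'
#' @param ensemble a `null_ensemble`.
#' @param map annotation `stat_map` on the ensemble's grid.
#' @param metric per-node metric vector.
#' @return numeric vector of null Spearman correlations (NA where a random
#'   network had an empty sphere, with a warning).
#' @export
ensemble_null_rho <- function(ensemble, map, metric = ensemble$metric) {
  vals <- vapply(ensemble$sphere_vox, function(spheres) {
    prof <- vapply(spheres, function(vox) {
      if (!length(vox)) return(NA_real_)
      mean(map$data[vox])
    }, 1)
    if (anyNA(prof) || stats::sd(prof) == 0) return(NA_real_)
    stats::cor(metric, prof, method = "spearman")
  }, 1)
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " random network(s) yielded an undefined ",
            "correlation")
  }
  vals
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble: %d networks of %d nodes, acceptance rate %.3g>\n",
    length(x$networks), nrow(x$networks[[1]]), x$acceptance_rate))
  invisible(x)
}

#' Permutation test against a random-network null
#'
#' One-sided test in the direction of the empirical correlation's sign: for
#' a positive empirical rho, `p` is the add-one fraction of null correlations
#' at least as large, and the result is significant iff the empirical value
#' exceeds the 95th percentile of the null (mirrored for negative rho).
#'
#' @param empirical_rho observed Spearman correlation.
#' @param ensemble a `null_ensemble` (or bare numeric vector of null rho).
#' @param level significance level (default 0.05).
#' @return list with `p`, `significant`, `direction` and the null quantile
#'   used as `critical`.
#' @export
null_test <- function(empirical_rho, ensemble, level = 0.05) {
  null_rho <- if (inherits(ensemble, "null_ensemble")) ensemble$null_rho
              else as.numeric(ensemble)
  null_rho <- null_rho[!is.na(null_rho)]
  if (!length(null_rho)) stop("empty null ensemble")
  n <- length(null_rho)
  if (empirical_rho >= 0) {
    b <- sum(null_rho >= empirical_rho)
    crit <- stats::quantile(null_rho, 1 - level, names = FALSE)
    sig <- empirical_rho > crit
  } else {
    b <- sum(null_rho <= empirical_rho)
    crit <- stats::quantile(null_rho, level, names = FALSE)
    sig <- empirical_rho < crit
  }
  list(p = (b + 1) / (n + 1), significant = sig,
       direction = if (empirical_rho >= 0) "positive" else "negative",
       critical = crit)
}
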