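#' Toy brain grid
#'
#' A small isotropic grid with an ellipsoidal "brain" mask, used throughout
#' the test-bench: large enough for kernels and clusters to fit, small enough
#' for Monte-Carlo loops.
#'
#' @param shape grid shape (default 40 x 48 x 40).
#' @param res isotropic voxel size, mm (default 2).
#' @param mask_fraction semi-axes of the ellipsoid mask as a fraction of the
#'   half-extent of the grid.
#' @export
toy_brain_grid <- function(shape = c(40, 48, 40), res = 2,
                           mask_fraction = 0.92) {
  g <- volume_grid(shape, res = res)
  semi <- (shape * res / 2) * mask_fraction
  volume_grid(shape, g$affine, ellipsoid_mask(g, c(0, 0, 0), semi))
}

#' Synthetic foci corpus with planted spatial convergence
#'
#' Emulates a coordinate-based meta-analysis corpus: each experiment hits
#' each planted cluster centre with probability `prob_hit`, contributing
#' `foci_per_cluster` foci jittered isotropically (Gaussian, sd `jitter_sd`
#' mm) around the centre, plus `noise_foci` foci drawn uniformly from the
#' mask. Sample sizes are uniform on `subjects_range`. All foci fall inside
#' the mask (jittered foci are rejection-sampled back in).
#'
#' Defaults are the package's reference conditions for planted-cluster
#' recovery: 20 experiments, one centre at the origin, 3 cluster foci and 5
#' uniform noise foci each, 5 mm jitter.
#'
#' @param grid a [volume_grid()].
#' @param n_experiments number of experiments (default 20).
#' @param cluster_centers matrix of planted centre coordinates in mm (one row
#'   per centre), or `NULL` for a plant-free corpus.
#' @param foci_per_cluster foci contributed per hit cluster (default 3).
#' @param prob_hit probability an experiment hits a given cluster (default
#'   0.9).
#' @param noise_foci uniform noise foci per experiment (default 5).
#' @param subjects_range inclusive integer range of sample sizes (default
#'   15-30).
#' @param jitter_sd isotropic jitter sd around cluster centres, mm (default
#'   5, the scale of ALE spatial uncertainty).
#' @param seed RNG seed; the generator is bit-reproducible given the seed.
#' @return An [experiment_set()].
#' @export
gen_foci_corpus <- function(grid, n_experiments = 20,
                            cluster_centers = matrix(c(0, 0, 0), 1),
                            foci_per_cluster = 3, prob_hit = 0.9,
                            noise_foci = 5, subjects_range = c(15, 30),
                            jitter_sd = 5, seed = 1) {
  stopifnot(n_experiments >= 1, foci_per_cluster >= 0, noise_foci >= 0,
            prob_hit >= 0, prob_hit <= 1)
  mask_idx <- which(grid$mask)
  vs <- voxel_size(grid)
  if (!is.null(cluster_centers)) {
    cluster_centers <- rbind_coerce(cluster_centers)
    cv <- nearest_voxel(grid, cluster_centers)
    ok <- in_bounds(grid, cv)
    ok[ok] <- grid$mask[ijk_to_linear(grid$shape, cv[ok, , drop = FALSE])]
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop(sprintf("cluster center (%g, %g, %g) lies outside the mask",
                   cluster_centers[bad, 1], cluster_centers[bad, 2],
                   cluster_centers[bad, 3]))
    }
  }
  inside <- function(xyz) {
    v <- nearest_voxel(grid, xyz)
    ok <- in_bounds(grid, v)
    ok[ok] <- grid$mask[ijk_to_linear(grid$shape, v[ok, , drop = FALSE])]
    ok
  }
  draw_cluster_foci <- function(center, m) {
    out <- matrix(NA_real_, m, 3)
    got <- 0L
    for (try in seq_len(1000L)) {
      need <- m - got
      cand <- matrix(stats::rnorm(need * 3, sd = jitter_sd), need, 3) +
        matrix(center, need, 3, byrow = TRUE)
      ok <- inside(cand)
      if (any(ok)) {
        take <- min(sum(ok), need)
        out[got + seq_len(take), ] <- cand[which(ok)[seq_len(take)], ]
        got <- got + take
      }
      if (got == m) return(out)
    }
    stop("could not place cluster foci inside the mask")
  }
  draw_noise_foci <- function(m) {
    vox <- arrayInd(sample(mask_idx, m, replace = TRUE), grid$shape)
    vox_to_mm(grid, vox) +
      matrix(stats::runif(m * 3, -0.5, 0.5), m, 3) *
        matrix(vs, m, 3, byrow = TRUE)
  }
  set.seed(seed)
  exps <- vector("list", n_experiments)
  for (e in seq_len(n_experiments)) {
    foci <- matrix(numeric(0), 0, 3)
    if (!is.null(cluster_centers) && foci_per_cluster > 0) {
      for (c in seq_len(nrow(cluster_centers))) {
        if (stats::runif(1) < prob_hit) {
          foci <- rbind(foci, draw_cluster_foci(cluster_centers[c, ],
                                                foci_per_cluster))
        }
      }
    }
    if (noise_foci > 0) foci <- rbind(foci, draw_noise_foci(noise_foci))
    if (!nrow(foci)) foci <- draw_noise_foci(1L)
    n_sub <- sample(subjects_range[1]:subjects_range[2], 1)
    exps[[e]] <- experiment(study_id = sprintf("synthstudy_%02d", e),
                            experiment_id = sprintf("synthexp_%02d", e),
                            contrast = "synthetic", n_subjects = n_sub,
                            foci = foci)
  }
  experiment_set(exps, provenance = "gen_foci_corpus")
}

#' Synthetic node layout with planted communities
#'
#' Places `n_nodes` nodes on a regular lattice (spacing `spacing_mm`) inside
#' a compact grid, and assigns them to `n_communities` contiguous blocks of
#' near-equal size. The grid is just large enough to hold every node sphere
#' -- this is the geometry used by the BOLD and annotation generators.
#'
#' @param n_nodes number of nodes (default 21, matching the impulsivity
#'   network).
#' @param n_communities planted community count (default 4).
#' @param spacing_mm lattice spacing (default 18, comfortably above the 15 mm
#'   peak-merging radius).
#' @param margin_mm margin around the lattice (default 10).
#' @param res voxel size, mm.
#' @return list with `grid` (all-in mask), `nodes` ([node_set()]) and
#'   `membership` (planted community labels).
#' @export
synthetic_network <- function(n_nodes = 21, n_communities = 4,
                              spacing_mm = 18, margin_mm = 10, res = 2) {
  side <- ceiling(sqrt(n_nodes))
  ij <- as.matrix(expand.grid(seq_len(side), seq_len(side)))[seq_len(n_nodes),
                                                             , drop = FALSE]
  xy <- (ij - (side + 1) / 2) * spacing_mm
  xyz <- cbind(xy, 0)
  half <- apply(abs(xyz), 2, max) + margin_mm
  shape <- ceiling(2 * half / res) + 1
  grid <- volume_grid(shape, res = res)
  membership <- rep(seq_len(n_communities),
                    each = ceiling(n_nodes / n_communities))[seq_len(n_nodes)]
  nodes <- node_set(data.frame(region = sprintf("synthnode_%02d",
                                                seq_len(n_nodes)),
                               hemisphere = "",
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  list(grid = grid, nodes = nodes, membership = membership)
}

block_covariance <- function(membership, within_r, between_r) {
  n <- length(membership)
  S <- matrix(between_r, n, n)
  same <- outer(membership, membership, "==")
  S[same] <- within_r
  diag(S) <- 1
  S
}

#' Synthetic multi-subject BOLD with planted block communities
#'
#' Node latent signals are drawn from a multivariate normal whose correlation
#' is `within_r` inside a planted community and `between_r` across
#' communities; every voxel inside a node's sphere carries that node's latent
#' signal plus independent white noise, and all remaining in-mask voxels are
#' pure noise. Empirical node-sphere correlations converge to the targets as
#' the number of timepoints grows. A per-subject motion trace of i.i.d.
#' half-normal framewise-displacement values is synthesised alongside.
#'
#' @param grid,nodes,membership typically from [synthetic_network()].
#' @param within_r,between_r target Pearson correlations (the implied
#'   covariance must be positive semi-definite: `-1 < between_r <= within_r
#'   < 1` necessary, checked by eigendecomposition).
#' @param n_timepoints timepoints per subject.
#' @param tr_seconds repetition time (default 1.4 s).
#' @param noise_sd voxel-level white-noise sd on top of the unit-variance
#'   latent signals (default 0.5).
#' @param sphere_radius_mm node sphere radius (default 5).
#' @param n_subjects number of subjects (default 1).
#' @param fd_mean target mean framewise displacement per subject, mm
#'   (recycled; default 0.2).
#' @param seed RNG seed; bit-reproducible.
#' @return list with `subjects` (each: `bold` 4D array, `motion`
#'   [motion_trace()]), `grid`, `nodes`, `membership`, `gm_mask` and
#'   `tr_seconds`.
#' @export
gen_bold <- function(grid, nodes, membership, within_r = 0.5,
                     between_r = 0.05, n_timepoints = 500, tr_seconds = 1.4,
                     noise_sd = 0.5, sphere_radius_mm = 5, n_subjects = 1,
                     fd_mean = 0.2, seed = 1) {
  stopifnot(within_r <= 1, within_r >= between_r, between_r > -1,
            n_timepoints >= 2, noise_sd >= 0)
  n <- nrow(nodes)
  stopifnot(length(membership) == n)
  S <- block_covariance(membership, within_r, between_r)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("implied node covariance is not positive semi-definite; ",
         "try a smaller (less negative) between_r")
  }
  Fac <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)
  spheres <- lapply(seq_len(n), function(i) {
    vox <- sphere_voxels(grid, node_coords(nodes)[i, ], sphere_radius_mm)
    if (!length(vox)) stop("node '", nodes$region[i], "' sphere is empty")
    vox
  })
  fd_mean <- rep_len(fd_mean, n_subjects)
  mask_idx <- which(grid$mask)
  nvox <- prod(grid$shape)
  set.seed(seed)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    Z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n) %*% t(Fac)
    M <- matrix(0, nvox, n_timepoints)
    M[mask_idx, ] <- stats::rnorm(length(mask_idx) * n_timepoints)
    for (i in seq_len(n)) {
      noise <- M[spheres[[i]], , drop = FALSE] * noise_sd
      M[spheres[[i]], ] <- matrix(Z[, i], length(spheres[[i]]),
                                  n_timepoints, byrow = TRUE) + noise
    }
    fd <- abs(stats::rnorm(n_timepoints,
                           sd = fd_mean[s] * sqrt(pi / 2)))
    subjects[[s]] <- list(bold = array(M, c(grid$shape, n_timepoints)),
                          motion = motion_trace(fd))
  }
  list(subjects = subjects, grid = grid, nodes = nodes,
       membership = membership, gm_mask = grid$mask,
       tr_seconds = tr_seconds)
}

#' Synthetic annotation map with planted metric coupling
#'
#' Builds a volumetric annotation (receptor-density-like) map whose
#' node-sphere mean values have a target Spearman rank correlation
#' (`coupling`) with a supplied node metric. Node target values are a
#' `coupling`-weighted mixture of the standardised metric ranks and fresh
#' noise; sphere voxels are set to the node value, the background is
#' `background_level` plus white noise, and the volume is optionally smoothed
#' to `smoothness_fwhm`. A construction loop redraws the noise until the
#' achieved sphere-mean rank correlation is within `tol` of `coupling`.
#'
#' @param grid,nodes typically from [synthetic_network()].
#' @param node_metric per-node metric driving the coupling (non-constant).
#' @param coupling target rank correlation, between -1 and 1.
#' @param smoothness_fwhm spatial smoothing FWHM, mm (0 = none).
#' @param background_level mean background value.
#' @param bg_noise_sd background white-noise sd (default 1).
#' @param radius_mm node-sphere radius used for writing values and for the
#'   construction check (default 2.5).
#' @param tol acceptance tolerance on the achieved rank correlation
#'   (default 0.15).
#' @param max_tries construction-loop attempts before giving up.
#' @param seed RNG seed; bit-reproducible.
#' @return A `stat_map` of kind `"density"` with attributes `achieved_rho`
#'   and `tries`.
#' @export
gen_annotation_map <- function(grid, nodes, node_metric, coupling = 0.8,
                               smoothness_fwhm = 0, background_level = 0,
                               bg_noise_sd = 1, radius_mm = 2.5, tol = 0.15,
                               max_tries = 100, seed = 1) {
  stopifnot(coupling >= -1, coupling <= 1)
  n <- nrow(nodes)
  stopifnot(length(node_metric) == n)
  if (stats::sd(node_metric) == 0) {
    stop("node_metric is constant: rank correlation with it is undefined")
  }
  ranks <- scale(rank(node_metric))[, 1]
  spheres <- lapply(seq_len(n), function(i) {
    vox <- sphere_voxels(grid, node_coords(nodes)[i, ], radius_mm)
    if (!length(vox)) stop("node '", nodes$region[i], "' sphere is empty")
    vox
  })
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    vals <- coupling * ranks +
      sqrt(max(0, 1 - coupling^2)) * scale(stats::rnorm(n))[, 1]
    arr <- array(background_level, grid$shape)
    arr[grid$mask] <- background_level +
      bg_noise_sd * stats::rnorm(sum(grid$mask))
    for (i in seq_len(n)) arr[spheres[[i]]] <- vals[i]
    if (smoothness_fwhm > 0) {
      arr <- gaussian_smooth(arr, smoothness_fwhm, voxel_size(grid))
    }
    means <- vapply(spheres, function(v) mean(arr[v]), 1)
    achieved <- stats::cor(means, node_metric, method = "spearman")
    if (abs(achieved - coupling) <= tol) {
      out <- stat_map(grid, arr, "density")
      attr(out, "achieved_rho") <- achieved
      attr(out, "tries") <- try
      return(out)
    }
  }
  stop("construction loop failed to reach the target coupling within ",
       max_tries, " tries (target ", coupling, ", tol ", tol, ")")
}
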