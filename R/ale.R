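#' ALE kernel specification
#'
#' The spatial uncertainty of a reported activation focus is modelled as an
#' isotropic 3D Gaussian whose variance is the sum of a between-template
#' component and a between-subject component shrunk by the experiment's sample
#' size: `sd(n) = sqrt(sigma_template^2 + sigma_subject^2 / n)`. Defaults
#' correspond to the empirical calibration in widespread use (between-template
#' FWHM 5.7 mm; single-subject between-subject FWHM 11.6 mm) and are fully
#' configurable.
#'
#' @param sigma_template_mm between-template standard deviation, mm.
#' @param sigma_subject_mm single-subject between-subject standard deviation,
#'   mm (divided by `sqrt(n)` for an experiment with `n` subjects).
#' @param truncation_radius_mm kernel truncation radius in mm, or `NULL`
#'   (default) to truncate at `truncation_sd` kernel standard deviations.
#' @param truncation_sd truncation radius in units of the kernel sd.
#' @export
kernel_spec <- function(sigma_template_mm = 5.7 / (2 * sqrt(2 * log(2))),
                        sigma_subject_mm = 11.6 / (2 * sqrt(2 * log(2))),
                        truncation_radius_mm = NULL,
                        truncation_sd = 4) {
  stopifnot(sigma_template_mm > 0, sigma_subject_mm > 0, truncation_sd > 0)
  structure(list(sigma_template_mm = sigma_template_mm,
                 sigma_subject_mm = sigma_subject_mm,
                 truncation_radius_mm = truncation_radius_mm,
                 truncation_sd = truncation_sd),
            class = "kernel_spec")
}

#' Sample-size-dependent kernel width
#'
#' @param n_subjects number of subjects in the experiment (>= 1).
#' @param spec a [kernel_spec()].
#' @return kernel standard deviation in mm; strictly decreasing in
#'   `n_subjects`.
#' @export
kernel_sd <- function(n_subjects, spec = kernel_spec()) {
  if (any(n_subjects < 1)) stop("n_subjects must be >= 1")
  sqrt(spec$sigma_template_mm^2 + spec$sigma_subject_mm^2 / n_subjects)
}

trunc_radius <- function(sd_mm, spec) {
  if (!is.null(spec$truncation_radius_mm)) spec$truncation_radius_mm
  else spec$truncation_sd * sd_mm
}

# Discrete Gaussian stencil on the grid's voxel lattice, spherically truncated
# and normalised so its discrete sum is exactly 1 (so each focus deposits unit
# probability mass on an unmasked grid).
kernel_stencil <- function(grid, sd_mm, spec) {
  vs <- voxel_size(grid)
  rad <- trunc_radius(sd_mm, spec)
  r <- pmax(1L, floor(rad / vs))
  dx <- lapply(1:3, function(a) (-r[a]:r[a]) * vs[a])
  K <- exp(-outer(outer(dx[[1]]^2, dx[[2]]^2, "+"), dx[[3]]^2, "+") /
             (2 * sd_mm^2))
  d2 <- outer(outer(dx[[1]]^2, dx[[2]]^2, "+"), dx[[3]]^2, "+")
  K[d2 > rad^2] <- 0
  K / sum(K)
}

# Max-combine a stencil into `map` at integer voxel centres (1-based ijk rows),
# clipping at the array edges.
place_stencils_max <- function(map, centers, K) {
  shape <- dim(map)
  r <- (dim(K) - 1L) %/% 2L
  for (f in seq_len(nrow(centers))) {
    c_ijk <- centers[f, ]
    lo <- pmax(1L, c_ijk - r)
    hi <- pmin(shape, c_ijk + r)
    slo <- lo - (c_ijk - r) + 1L
    shi <- slo + (hi - lo)
    box <- map[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    map[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      pmax(box, K[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]])
  }
  map
}

#' Modelled-activation (MA) map of one experiment
#'
#' Each focus is modelled as the centre of a truncated 3D Gaussian probability
#' kernel (see [kernel_spec()]); the per-voxel MA value is the *maximum* over
#' the experiment's foci, so several nearby foci reported by one experiment do
#' not inflate the activation probability beyond that of a single focus.
#'
#' @param exp an [experiment()].
#' @param grid a [volume_grid()].
#' @param spec a [kernel_spec()].
#' @return A [stat_map()] of kind `"MA"`.
#' @export
ma_map <- function(exp, grid, spec = kernel_spec()) {
  centers <- nearest_voxel(grid, exp$foci)
  if (!all(in_bounds(grid, centers))) {
    bad <- which(!in_bounds(grid, centers))[1]
    stop(sprintf("focus (%g, %g, %g) lies outside the grid bounding box",
                 exp$foci[bad, 1], exp$foci[bad, 2], exp$foci[bad, 3]))
  }
  li <- ijk_to_linear(grid$shape, centers)
  if (!all(grid$mask[li])) {
    warning(sprintf("%d focus/foci of experiment '%s' lie outside the mask",
                    sum(!grid$mask[li]), exp$experiment_id))
  }
  sd_mm <- kernel_sd(exp$n_subjects, spec)
  K <- kernel_stencil(grid, sd_mm, spec)
  map <- place_stencils_max(array(0, grid$shape), centers, K)
  stat_map(grid, map, "MA")
}

#' ALE map from modelled-activation maps
#'
#' The ALE score is the union of the experiments' activation probabilities,
#' `ALE(v) = 1 - prod_i (1 - MA_i(v))`: the probability that at least one
#' experiment activates voxel `v` under independence.
#'
#' @param ma_maps list of `stat_map` objects of kind `"MA"` on a shared grid.
#' @return A [stat_map()] of kind `"ALE"`.
#' @export
ale_map <- function(ma_maps) {
  stopifnot(length(ma_maps) >= 1)
  g <- ma_maps[[1]]$grid
  acc <- array(1, g$shape)
  for (m in ma_maps) {
    if (!same_grid(m$grid, g)) stop("MA maps must share a grid")
    acc <- acc * (1 - m$data)
  }
  stat_map(g, 1 - acc, "ALE")
}

#' Analytic ALE null distribution
#'
#' Exact distribution of the ALE score under random spatial association: for
#' each experiment take the histogram of its MA values over in-mask voxels
#' (zeros included), then combine histograms sequentially under the union rule
#' `s = 1 - (1 - a)(1 - b)` with probability-mass products, re-binning at
#' `bin_width`. This is the distribution of ALE at a voxel when every
#' experiment's map is sampled at an independent uniformly random voxel.
#'
#' @param ma_maps list of MA `stat_map`s on a shared grid.
#' @param bin_width ALE-score histogram resolution.
#' @param tail_floor bins beyond the point where the survival function drops
#'   below this value are folded into the last retained bin, bounding the
#'   combination cost; p values are exact above it.
#' @return A `null_distribution`: probability mass `prob` over bin values
#'   `value = (seq_along(prob) - 1) * bin_width`.
#' @export
analytic_null <- function(ma_maps, bin_width = 1e-5, tail_floor = 1e-10) {
  stopifnot(length(ma_maps) >= 1, bin_width > 0)
  hists <- lapply(ma_maps, function(m) {
    v <- masked_values(m)
    idx <- as.integer(round(v / bin_width))
    tab <- rowsum(rep.int(1 / length(v), length(v)), idx)
    list(idx = as.integer(rownames(tab)), w = as.numeric(tab))
  })
  max_ale <- 1 - prod(vapply(hists, function(h) 1 - max(h$idx) * bin_width, 1))
  # margin absorbs per-experiment rounding drift in the sequential re-binning
  nbin <- as.integer(round(max_ale / bin_width)) + length(hists) + 2L
  prob <- numeric(nbin)
  prob[hists[[1]]$idx + 1L] <- hists[[1]]$w
  for (h in hists[-1]) {
    nz <- which(prob > 0)
    a <- (nz - 1L) * bin_width
    p <- prob[nz]
    new <- numeric(nbin)
    for (j in seq_along(h$idx)) {
      m <- h$idx[j] * bin_width
      idx_s <- pmin(as.integer(round((m + (1 - m) * a) / bin_width)) + 1L,
                    nbin)
      contrib <- rowsum(h$w[j] * p, idx_s)
      at <- as.integer(rownames(contrib))
      new[at] <- new[at] + as.numeric(contrib)
    }
    # fold the ultra-far tail into its first bin: keeps total mass exact
    # while bounding the cost of subsequent combinations
    sv <- rev(cumsum(rev(new)))
    last <- max(which(sv > tail_floor))
    if (last < length(new)) {
      new[last] <- sv[last]
      new <- new[seq_len(last)]
    }
    prob <- new
  }
  if (length(prob) < nbin) prob <- c(prob, numeric(nbin - length(prob)))
  structure(list(bin_width = bin_width, prob = prob,
                 value = (seq_along(prob) - 1) * bin_width,
                 surv = rev(cumsum(rev(prob)))),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution: %d bins of width %g, mass %.9f, max ALE %.4g>\n",
    length(x$prob), x$bin_width, sum(x$prob), max(x$value[x$prob > 0])))
  invisible(x)
}

#' Null survival probability of ALE scores
#'
#' `P(ALE_null >= x)` from a [analytic_null()] distribution. The binned
#' survival function is interpolated linearly between bin values, so
#' continuous observed scores are not snapped to the nearest atom (which
#' would bias tail p values by up to half a bin).
#'
#' @param null a `null_distribution`.
#' @param x ALE scores.
#' @return survival probabilities in (0, 1].
#' @export
null_survival <- function(null, x) {
  s <- stats::approx(null$value, null$surv, xout = x, rule = 2)$y
  pmin(pmax(s, 1e-24), 1)
}

#' Smallest ALE score significant at a voxel-level threshold
#'
#' @param null a `null_distribution`.
#' @param p_voxel voxel-level threshold in (0, 1).
#' @return the smallest binned ALE value whose survival probability is below
#'   `p_voxel` (`Inf` when no bin reaches it).
#' @export
ale_cutoff <- function(null, p_voxel) {
  ok <- which(null$surv < p_voxel)
  if (!length(ok)) return(Inf)
  null$value[ok[1]]
}

#' Voxel-level thresholding against the analytic null
#'
#' A voxel is retained iff its null survival probability is strictly below
#' `p_voxel`. Also returns the voxel-wise p map and its inverse-normal
#' z-equivalent for downstream peak extraction.
#'
#' @param ale a `stat_map` of kind `"ALE"`.
#' @param null a `null_distribution` from [analytic_null()].
#' @param p_voxel voxel-level threshold (default 0.001).
#' @return list with `label` (binary `stat_map`), `p` (`stat_map` of p
#'   values), `z` (`stat_map` of z equivalents) and the ALE `cutoff`.
#' @export
voxel_threshold <- function(ale, null, p_voxel = 0.001) {
  stopifnot(p_voxel > 0, p_voxel <= 1)
  g <- ale$grid
  p <- array(1, g$shape)
  p[g$mask] <- null_survival(null, ale$data[g$mask])
  lab <- array(0, g$shape)
  # p values live in (0, 1], so p_voxel = 1 retains every masked voxel
  lab[g$mask & (p < p_voxel | p_voxel >= 1)] <- 1
  z <- array(0, g$shape)
  z[g$mask] <- stats::qnorm(1 - p[g$mask])
  list(label = stat_map(g, lab, "label"),
       p = stat_map(g, p, "P"),
       z = stat_map(g, z, "Z"),
       cutoff = ale_cutoff(null, p_voxel))
}

# Uniformly redraw every experiment's foci (same counts, same sample sizes)
# at random in-mask voxel centres; returns per-experiment ijk matrices.
redraw_foci_ijk <- function(set, grid) {
  mask_idx <- which(grid$mask)
  lapply(set$experiments, function(e) {
    s <- sample(mask_idx, nrow(e$foci), replace = TRUE)
    arrayInd(s, grid$shape)
  })
}

#' Cluster-level family-wise error correction
#'
#' Monte-Carlo null of the maximum cluster extent: each iteration redraws
#' every experiment's foci uniformly at random within the mask (same focus
#' counts, same sample sizes, hence same kernels), recomputes the ALE map,
#' applies the voxel-level ALE cutoff, and records the size of the largest
#' connected component. Observed clusters are retained iff their extent
#' exceeds the `1 - p_cluster` quantile of that null.
#'
#' @param experiments an [experiment_set()].
#' @param grid a [volume_grid()].
#' @param spec a [kernel_spec()].
#' @param p_voxel voxel-level cluster-inclusion threshold.
#' @param p_cluster cluster-level family-wise error rate.
#' @param n_iter Monte-Carlo iterations (>= 100).
#' @param seed RNG seed (the Monte-Carlo resampling is the only randomness).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default).
#' @param bin_width analytic-null resolution.
#' @return list with `clusters` (data.frame: label, extent, peak mm
#'   coordinates, peak ALE value, cluster-level p), `label` (`stat_map` of
#'   surviving clusters), `ale`, `null`, `threshold` (the
#'   [voxel_threshold()] output) and `max_null_sizes`.
#' @export
cluster_fwe <- function(experiments, grid, spec = kernel_spec(),
                        p_voxel = 0.001, p_cluster = 0.05, n_iter = 1000,
                        seed = 1, connectivity = 26, bin_width = 1e-5) {
  if (n_iter < 100) stop("n_iter must be >= 100")
  if (n_iter < 1 / p_cluster) {
    warning("n_iter is small for the requested cluster-level quantile")
  }
  ma <- lapply(experiments$experiments, ma_map, grid = grid, spec = spec)
  ale <- ale_map(ma)
  null <- analytic_null(ma, bin_width)
  thr <- voxel_threshold(ale, null, p_voxel)
  cutoff <- thr$cutoff

  stencils <- lapply(experiments$experiments, function(e) {
    kernel_stencil(grid, kernel_sd(e$n_subjects, spec), spec)
  })
  set.seed(seed)
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    centers <- redraw_foci_ijk(experiments, grid)
    acc <- array(1, grid$shape)
    for (j in seq_along(centers)) {
      m <- place_stencils_max(array(0, grid$shape), centers[[j]],
                              stencils[[j]])
      acc <- acc * (1 - m)
    }
    supra <- grid$mask & (1 - acc) >= cutoff
    max_sizes[it] <- if (any(supra)) max(tabulate(label_components(supra,
                                                                   connectivity)))
                     else 0L
  }
  crit <- sort(max_sizes)[ceiling((1 - p_cluster) * n_iter)]

  lab_all <- label_components(thr$label$data > 0, connectivity)
  sizes <- tabulate(lab_all)
  keep <- which(sizes > crit)
  out_lab <- array(0, grid$shape)
  rows <- list()
  for (i in seq_along(keep)) {
    k <- keep[i]
    vox <- which(lab_all == k)
    out_lab[vox] <- i
    pk <- vox[which.max(ale$data[vox])]
    pk_mm <- vox_to_mm(grid, arrayInd(pk, grid$shape))
    rows[[i]] <- data.frame(label = i, extent = sizes[k],
                            peak_x = pk_mm[1], peak_y = pk_mm[2],
                            peak_z = pk_mm[3],
                            peak_ale = ale$data[pk],
                            p_cluster = (sum(max_sizes >= sizes[k]) + 1) /
                              (n_iter + 1))
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), extent = integer(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0),
               peak_ale = numeric(0), p_cluster = numeric(0))
  list(clusters = clusters,
       label = stat_map(grid, out_lab, "label"),
       ale = ale, null = null, threshold = thr,
       critical_extent = crit, max_null_sizes = max_sizes)
}

#' Full ALE meta-analysis
#'
#' Convenience chain: MA maps, ALE map, analytic null, voxel-level threshold
#' and Monte-Carlo cluster-level FWE correction.
#'
#' @inheritParams cluster_fwe
#' @return see [cluster_fwe()].
#' @export
run_ale <- function(experiments, grid, spec = kernel_spec(),
                    p_voxel = 0.001, p_cluster = 0.05, n_iter = 1000,
                    seed = 1, connectivity = 26, bin_width = 1e-5) {
  cluster_fwe(experiments, grid, spec, p_voxel, p_cluster, n_iter, seed,
              connectivity, bin_width)
}
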