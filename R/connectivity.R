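#' Framewise displacement (Power convention)
#'
#' Per-frame head-motion summary: the sum of absolute frame-to-frame
#' differences of the six rigid-body parameters, with the three rotations
#' (radians) converted to arc length on a 50 mm sphere. The first frame has
#' FD 0 by convention.
#'
#' @param params T x 6 matrix: three translations (mm) then three rotations
#'   (radians).
#' @param rotation_radius_mm sphere radius for the rotation-to-mm conversion.
#' @return A `motion_trace`: list with `fd` (length T, mm) and `mean_fd`.
#' @export
framewise_displacement <- function(params, rotation_radius_mm = 50) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6L, nrow(params) >= 1L)
  d <- abs(diff(params))
  d[, 4:6] <- d[, 4:6] * rotation_radius_mm
  motion_trace(c(0, rowSums(d)))
}

#' @rdname framewise_displacement
#' @param fd numeric vector of non-negative per-frame FD values (mm).
#' @export
motion_trace <- function(fd) {
  if (!length(fd)) stop("empty motion trace")
  if (any(fd < 0)) stop("FD must be non-negative")
  structure(list(fd = fd, mean_fd = mean(fd)), class = "motion_trace")
}

#' Motion-based subject exclusion
#'
#' A subject is kept iff their mean framewise displacement is less than or
#' equal to `threshold_mm` (boundary values are kept).
#'
#' @param traces list of `motion_trace` objects.
#' @param threshold_mm mean-FD threshold in mm (e.g. 0.5 for a lenient
#'   discovery-style cut, 0.2 for a strict replication-style cut).
#' @return integer vector of kept subject indices.
#' @export
fd_filter <- function(traces, threshold_mm) {
  stopifnot(threshold_mm > 0)
  mfd <- vapply(traces, function(tr) {
    if (!inherits(tr, "motion_trace")) tr <- motion_trace(tr)
    tr$mean_fd
  }, 1)
  which(mfd <= threshold_mm)
}

# Residualise the columns of Y (T x V) on a confound matrix (intercept
# added); collinear confound columns are dropped with a warning.
residualise <- function(Y, confounds) {
  X <- cbind(intercept = 1, as.matrix(confounds))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warning("dropping ", length(drop), " collinear confound column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  Y - X %*% qr.coef(qrX, Y)
}

#' Nuisance denoising of a 4D BOLD volume
#'
#' In order: (1) voxel-wise regression of the supplied confound traces
#' (typically white-matter, CSF and global-signal means) with an intercept;
#' (2) linear detrending; (3) zero-phase band-pass filtering (Butterworth,
#' order 2, applied forwards and backwards) within `band`; (4) spatial
#' Gaussian smoothing at `smooth_fwhm` mm.
#'
#' @param bold 4D array (x, y, z, time).
#' @param grid the [volume_grid()] of the spatial dimensions.
#' @param confounds T x k matrix of nuisance traces (may be `NULL`).
#' @param tr_seconds repetition time in seconds.
#' @param band band-pass limits in Hz (default 0.01-0.1).
#' @param smooth_fwhm spatial smoothing FWHM in mm (0 disables).
#' @return denoised 4D array of the same shape.
#' @export
denoise <- function(bold, grid, confounds = NULL, tr_seconds,
                    band = c(0.01, 0.1), smooth_fwhm = 5) {
  dm <- dim(bold)
  stopifnot(length(dm) == 4L, all(dm[1:3] == grid$shape))
  nt <- dm[4]
  Y <- t(matrix(bold, prod(dm[1:3]), nt))  # T x V
  if (!is.null(confounds)) {
    if (nrow(as.matrix(confounds)) != nt) {
      stop("confound traces must match the timepoint count")
    }
    Y <- residualise(Y, confounds)
  }
  Y <- residualise(Y, matrix(seq_len(nt), ncol = 1))  # linear detrend
  nyq <- 1 / (2 * tr_seconds)
  wl <- pmin(pmax(band / nyq, 1e-6), 1 - 1e-6)
  bf <- signal::butter(2, wl, type = "pass")
  Y <- apply(Y, 2, function(col) signal::filtfilt(bf, col))
  out <- array(t(Y), dm)
  if (smooth_fwhm > 0) {
    vs <- voxel_size(grid)
    for (t in seq_len(nt)) {
      out[, , , t] <- gaussian_smooth(out[, , , t], smooth_fwhm, vs)
    }
  }
  out
}

#' Node-sphere time series
#'
#' Each node's time series is the mean over grey-matter voxels whose centres
#' lie within `radius_mm` of the node coordinate.
#'
#' @param bold 4D array (x, y, z, time).
#' @param grid the [volume_grid()] of the spatial dimensions.
#' @param nodes a [node_set()].
#' @param gm_mask optional grey-matter mask (defaults to the grid mask).
#' @param radius_mm sphere radius in mm (default 5).
#' @param tr_seconds repetition time, carried along as an attribute.
#' @return `node_ts`: nodes x timepoints matrix with node regions as row
#'   names and attribute `tr_seconds`.
#' @export
sphere_timeseries <- function(bold, grid, nodes, gm_mask = NULL,
                              radius_mm = 5, tr_seconds = NA_real_) {
  dm <- dim(bold)
  stopifnot(length(dm) == 4L, all(dm[1:3] == grid$shape))
  if (is.null(gm_mask)) gm_mask <- grid$mask
  M <- matrix(bold, prod(dm[1:3]), dm[4])
  xyz <- node_coords(nodes)
  ts <- matrix(NA_real_, nrow(nodes), dm[4])
  for (i in seq_len(nrow(nodes))) {
    vox <- sphere_voxels(grid, xyz[i, ], radius_mm, gm_mask)
    if (!length(vox)) {
      stop(sprintf("node '%s' has an empty sphere (radius %g mm)",
                   nodes$region[i], radius_mm))
    }
    ts[i, ] <- colMeans(M[vox, , drop = FALSE])
  }
  rownames(ts) <- nodes$region
  attr(ts, "tr_seconds") <- tr_seconds
  class(ts) <- c("node_ts", class(ts))
  ts
}

# Fisher z with |r| clipped just inside (-1, 1) so perfectly correlated
# (e.g. duplicated) series stay finite.
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Group functional-connectivity matrix
#'
#' Per subject: Pearson correlation between node time courses, Fisher
#' z-transformed (with |r| clipped at 1 - 1e-7); then element-wise mean
#' across subjects. The diagonal is set to 0 by convention (self-connections
#' are undefined and ignored by all downstream graph measures).
#'
#' @param ts_per_subject list of nodes x timepoints matrices with identical
#'   node order.
#' @return symmetric nodes x nodes matrix of mean Fisher-z values.
#' @export
fc_matrix <- function(ts_per_subject) {
  stopifnot(length(ts_per_subject) >= 1)
  n <- nrow(ts_per_subject[[1]])
  acc <- matrix(0, n, n)
  for (ts in ts_per_subject) {
    stopifnot(nrow(ts) == n, ncol(ts) >= 2)
    sds <- apply(ts, 1, stats::sd)
    if (any(sds == 0)) {
      warning("zero-variance node series: ",
              paste(which(sds == 0), collapse = ", "),
              "; their edges are set to NA for this subject")
    }
    r <- suppressWarnings(stats::cor(t(ts)))
    z <- fisher_z(r)
    acc <- acc + z
  }
  out <- acc / length(ts_per_subject)
  out <- (out + t(out)) / 2
  diag(out) <- 0
  dimnames(out) <- list(rownames(ts_per_subject[[1]]),
                        rownames(ts_per_subject[[1]]))
  out
}

#' Seed-to-voxel connectivity maps
#'
#' For every node: per-subject Pearson correlation between the node's sphere
#' time course and every grey-matter voxel, Fisher z-transformed, then
#' averaged across subjects.
#'
#' @param bold_per_subject list of 4D arrays.
#' @param grid the shared [volume_grid()].
#' @param nodes a [node_set()].
#' @param gm_mask optional grey-matter mask (defaults to the grid mask).
#' @param radius_mm node-sphere radius in mm (default 5).
#' @return A `seed_map_set`: list with `maps` (nodes x n_gm_voxels matrix of
#'   group-mean Fisher-z values), `vox` (linear voxel indices), `grid`,
#'   `gm_mask` and `nodes`.
#' @export
seed_to_voxel <- function(bold_per_subject, grid, nodes, gm_mask = NULL,
                          radius_mm = 5) {
  if (is.null(gm_mask)) gm_mask <- grid$mask
  vox <- which(gm_mask & grid$mask)
  n <- nrow(nodes)
  acc <- matrix(0, n, length(vox))
  for (bold in bold_per_subject) {
    ts <- sphere_timeseries(bold, grid, nodes, gm_mask, radius_mm)
    M <- matrix(bold, prod(grid$shape), dim(bold)[4])[vox, , drop = FALSE]
    r <- suppressWarnings(stats::cor(t(ts), t(M)))
    acc <- acc + fisher_z(r)
  }
  structure(list(maps = acc / length(bold_per_subject), vox = vox,
                 grid = grid, gm_mask = gm_mask, nodes = nodes),
            class = "seed_map_set")
}

#' @export
print.seed_map_set <- function(x, ...) {
  cat(sprintf("<seed_map_set: %d nodes x %d grey-matter voxels>\n",
              nrow(x$maps), ncol(x$maps)))
  invisible(x)
}
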