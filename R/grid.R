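#' Volume grids
#'
#' A `volume_grid` couples a 3D array shape with a voxel-to-world affine and a
#' logical in-brain mask. All world coordinates are MNI-style millimetres; the
#' affine maps *0-based* voxel indices (the NIfTI convention) to mm. R-side
#' array indices are 1-based and converted internally.
#'
#' @param shape integer vector of length 3.
#' @param affine 4x4 voxel-to-mm matrix; defaults to an isotropic grid of
#'   resolution `res` centred on the origin.
#' @param mask logical array of dimension `shape`; default all `TRUE`.
#' @param res isotropic voxel size in mm used when `affine` is missing.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine = NULL, mask = NULL, res = 2) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    affine <- diag(c(rep(res, 3), 1))
    affine[1:3, 4] <- -(shape - 1L) * res / 2
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be invertible")
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dim = shape)
  }
  stopifnot(is.logical(mask), all(dim(mask) == shape))
  if (!any(mask)) stop("mask must contain at least one voxel")
  structure(list(shape = shape, affine = affine, mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, %d/%d voxels in mask, voxel size %s mm>\n",
              paste(x$shape, collapse = "x"), sum(x$mask),
              prod(x$shape),
              paste(signif(voxel_size(x), 3), collapse = "x")))
  invisible(x)
}

#' MNI152-like grid
#'
#' Standard 2 mm MNI bounding box (91 x 109 x 91 at `res = 2`) with the usual
#' corner offset of (-90, -126, -72) mm.
#'
#' @param res isotropic voxel size in mm.
#' @param mask optional logical array.
#' @export
mni_grid <- function(res = 2, mask = NULL) {
  shape <- as.integer(ceiling(c(181, 217, 181) / res))
  affine <- diag(c(rep(res, 3), 1))
  affine[1:3, 4] <- c(-90, -126, -72)
  volume_grid(shape, affine, mask)
}

#' Ellipsoid mask on a grid
#'
#' Convenience brain-like mask: voxels whose centres fall inside an ellipsoid.
#'
#' @param grid a `volume_grid`.
#' @param center_mm ellipsoid centre.
#' @param semiaxes_mm semi-axis lengths (length 3, mm).
#' @return logical array of the grid's shape.
#' @export
ellipsoid_mask <- function(grid, center_mm = c(0, 0, 0), semiaxes_mm) {
  stopifnot(length(semiaxes_mm) == 3L)
  xyz <- grid_coords(grid, masked = FALSE)
  d <- sweep(xyz, 2, center_mm)
  d <- sweep(d, 2, semiaxes_mm, "/")
  array(rowSums(d^2) <= 1, dim = grid$shape)
}

#' @rdname volume_grid
#' @param grid a `volume_grid`.
#' @export
voxel_size <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Coordinate transforms between voxel indices and mm
#'
#' `vox_to_mm` maps 1-based array indices to world mm; `mm_to_vox` maps mm to
#' continuous 1-based voxel coordinates; `nearest_voxel` snaps mm coordinates
#' to the closest voxel's integer index.
#'
#' @param grid a `volume_grid`.
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @param xyz n x 3 matrix of mm coordinates.
#' @return n x 3 matrix.
#' @export
vox_to_mm <- function(grid, ijk) {
  ijk <- rbind_coerce(ijk)
  h <- cbind(ijk - 1, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' @rdname vox_to_mm
#' @export
mm_to_vox <- function(grid, xyz) {
  xyz <- rbind_coerce(xyz)
  h <- cbind(xyz, 1) %*% t(solve(grid$affine))
  h[, 1:3, drop = FALSE] + 1
}

#' @rdname vox_to_mm
#' @export
nearest_voxel <- function(grid, xyz) {
  v <- round(mm_to_vox(grid, xyz))
  storage.mode(v) <- "integer"
  v
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  as.matrix(x)
}

in_bounds <- function(grid, ijk) {
  ijk[, 1] >= 1 & ijk[, 1] <= grid$shape[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= grid$shape[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= grid$shape[3]
}

ijk_to_linear <- function(shape, ijk) {
  (ijk[, 3] - 1L) * (shape[1] * shape[2]) + (ijk[, 2] - 1L) * shape[1] + ijk[, 1]
}

#' World coordinates of grid voxels
#'
#' @param grid a `volume_grid`.
#' @param masked if `TRUE` (default) return only in-mask voxel centres, in
#'   linear-index order.
#' @return n x 3 matrix of mm coordinates.
#' @export
grid_coords <- function(grid, masked = TRUE) {
  idx <- if (masked) which(grid$mask) else seq_len(prod(grid$shape))
  vox_to_mm(grid, arrayInd(idx, grid$shape))
}

#' Voxels within a sphere
#'
#' Linear indices of voxels whose centres lie within `radius_mm` of
#' `center_mm`, optionally restricted to an eligibility mask.
#'
#' @param grid a `volume_grid`.
#' @param center_mm sphere centre (mm).
#' @param radius_mm sphere radius (mm).
#' @param mask optional logical array restricting eligibility (defaults to the
#'   grid mask).
#' @return integer vector of linear indices (possibly empty).
#' @export
sphere_voxels <- function(grid, center_mm, radius_mm, mask = NULL) {
  if (is.null(mask)) mask <- grid$mask
  vs <- voxel_size(grid)
  c_vox <- mm_to_vox(grid, center_mm)[1, ]
  lo <- pmax(1L, floor(c_vox - radius_mm / vs))
  hi <- pmin(grid$shape, ceiling(c_vox + radius_mm / vs))
  if (any(lo > hi)) return(integer(0))
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  xyz <- vox_to_mm(grid, ijk)
  d2 <- rowSums(sweep(xyz, 2, center_mm)^2)
  keep <- d2 <= radius_mm^2
  li <- ijk_to_linear(grid$shape, ijk[keep, , drop = FALSE])
  li[mask[li]]
}

#' Connected-component labelling of a 3D logical array
#'
#' Breadth-first labelling under 6-, 18- or 26-neighbour connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @return integer array of the same shape; 0 = background, components
#'   labelled 1..k in order of first (linear-index) appearance.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  dm <- dim(mask)
  stopifnot(length(dm) == 3L)
  lab <- array(0L, dm)
  active <- which(mask)
  if (!length(active)) return(lab)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  man <- rowSums(abs(off))
  off <- off[man >= 1 & man <= switch(as.character(connectivity),
                                      "6" = 1, "18" = 2, "26" = 3), ,
             drop = FALSE]
  noff <- nrow(off)
  cur <- 0L
  for (s in active) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- arrayInd(s, dm)
    while (nrow(frontier)) {
      nf <- nrow(frontier)
      cand <- frontier[rep(seq_len(nf), each = noff), , drop = FALSE] +
        off[rep(seq_len(noff), nf), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
        cand[, 2] >= 1 & cand[, 2] <= dm[2] &
        cand[, 3] >= 1 & cand[, 3] <= dm[3]
      cand <- cand[ok, , drop = FALSE]
      li <- unique(ijk_to_linear(dm, cand))
      li <- li[mask[li] & lab[li] == 0L]
      if (!length(li)) break
      lab[li] <- cur
      frontier <- arrayInd(li, dm)
    }
  }
  lab
}

#' Separable 3D Gaussian smoothing
#'
#' Truncated (4 sigma) Gaussian convolution applied along each axis, with
#' kernel renormalisation at the array edges so a constant input stays
#' constant.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, mm.
#' @param voxdim voxel sizes along the three axes, mm.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(arr, fwhm_mm, voxdim) {
  if (fwhm_mm <= 0) return(arr)
  dm <- dim(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    s_vox <- sigma / voxdim[ax]
    r <- max(1L, ceiling(4 * s_vox))
    n <- dm[ax]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) ifelse(abs(i - j) <= r,
                                     exp(-(i - j)^2 / (2 * s_vox^2)), 0))
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = dm[ax])
    m <- K %*% m
    a <- array(m, dim = dm[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Statistic maps on a grid
#'
#' A `stat_map` holds one value per voxel of a [volume_grid()], tagged with
#' what the values are: a modelled-activation probability (`"MA"`), an ALE
#' score (`"ALE"`), a z statistic (`"Z"`), a p value (`"P"`) or an integer
#' cluster label (`"label"`).
#'
#' @param grid a `volume_grid`.
#' @param data numeric array of the grid's shape (values outside the mask are
#'   kept but ignored by masked operations).
#' @param kind one of `"MA"`, `"ALE"`, `"Z"`, `"P"`, `"label"`, `"density"`.
#' @export
stat_map <- function(grid, data, kind) {
  stopifnot(inherits(grid, "volume_grid"),
            all(dim(data) == grid$shape),
            kind %in% c("MA", "ALE", "Z", "P", "label", "density"))
  v <- data[grid$mask]
  if (kind %in% c("MA", "ALE") && any(v < 0 | v >= 1)) {
    stop(kind, " values must lie in [0, 1)")
  }
  if (kind == "P" && any(v <= 0 | v > 1)) stop("P values must lie in (0, 1]")
  structure(list(grid = grid, data = data, kind = kind), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$data[x$grid$mask]
  cat(sprintf("<stat_map kind=%s, range [%.4g, %.4g] over %d masked voxels>\n",
              x$kind, min(v), max(v), length(v)))
  invisible(x)
}

#' Masked values of a stat_map
#'
#' @param map a `stat_map`.
#' @return numeric vector, one value per in-mask voxel (linear-index order).
#' @export
masked_values <- function(map) {
  map$data[map$grid$mask]
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$affine, b$affine))
}

#' NIfTI-1 input/output
#'
#' Thin wrappers around \pkg{RNifti}: `write_volume` stores a `stat_map` (or a
#' bare array with a grid) as NIfTI-1; `read_volume` loads one into an array
#' plus `volume_grid` whose mask marks finite, non-zero voxels unless
#' `mask_all` is set.
#'
#' @param x a `stat_map`, or a numeric array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param grid required when `x` is a bare array.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "stat_map")) {
    grid <- x$grid
    x <- x$data
  }
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(x)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param mask_all if `TRUE` the returned grid masks every voxel; otherwise
#'   finite non-zero voxels.
#' @return `read_volume`: list with `data` (array) and `grid`.
#' @export
read_volume <- function(path, mask_all = TRUE) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  aff <- matrix(RNifti::xform(img), 4, 4)
  mask <- if (mask_all) NULL else array(is.finite(data) & data != 0, dim(data))
  list(data = data, grid = volume_grid(dim(data), aff, mask))
}
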