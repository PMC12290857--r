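#' Conjunction of two thresholded maps
#'
#' Voxel-wise intersection of two thresholded (binary or label) statistic
#' maps, with connected components smaller than `min_extent` voxels removed.
#'
#' @param map_a,map_b `stat_map`s on the same grid; non-zero voxels are taken
#'   as significant.
#' @param min_extent minimum cluster extent in voxels (default 5).
#' @param connectivity cluster connectivity (6/18/26).
#' @return list with `label` (`stat_map` of surviving intersection clusters)
#'   and `clusters` (data.frame: label, extent).
#' @export
conjunction <- function(map_a, map_b, min_extent = 5, connectivity = 26) {
  if (!same_grid(map_a$grid, map_b$grid)) stop("maps must share a grid")
  g <- map_a$grid
  inter <- (map_a$data != 0) & (map_b$data != 0) & g$mask
  lab <- label_components(inter, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_extent)
  out <- array(0, g$shape)
  rows <- list()
  for (i in seq_along(keep)) {
    out[lab == keep[i]] <- i
    rows[[i]] <- data.frame(label = i, extent = sizes[keep[i]])
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), extent = integer(0))
  list(label = stat_map(g, out, "label"), clusters = clusters)
}

# log(1 - MA) rows for a list of experiments; columns are the voxels in `vox`.
log_ma_matrix <- function(set, grid, spec, vox) {
  t(vapply(set$experiments, function(e) {
    log1p(-ma_map(e, grid, spec)$data[vox])
  }, numeric(length(vox))))
}

surviving_components <- function(sig_arr, grid, min_extent, connectivity,
                                 score_arr) {
  lab <- label_components(sig_arr, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_extent)
  out <- array(0, grid$shape)
  rows <- list()
  for (i in seq_along(keep)) {
    vox <- which(lab == keep[i])
    out[vox] <- i
    pk <- vox[which.max(score_arr[vox])]
    pk_mm <- vox_to_mm(grid, arrayInd(pk, grid$shape))
    rows[[i]] <- data.frame(label = i, extent = sizes[keep[i]],
                            peak_x = pk_mm[1], peak_y = pk_mm[2],
                            peak_z = pk_mm[3], peak_score = score_arr[pk])
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), extent = integer(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0),
               peak_score = numeric(0))
  list(label = stat_map(grid, out, "label"), clusters = clusters)
}

#' Meta-analytic contrast by label permutation
#'
#' The observed statistic is the voxel-wise difference of the two groups' ALE
#' scores. Its null is built by pooling all experiments and randomly
#' re-dividing them into two groups of the original sizes; voxel-wise
#' non-parametric p values use the add-one estimator `(b + 1) / (n + 1)`.
#' Voxels with `p < p_thresh` are kept and components below `min_extent`
#' voxels are discarded.
#'
#' Evaluation can be restricted to a mask (conventionally the union of the two
#' analyses' cluster-FWE-significant voxels); with `restrict_mask = NULL` the
#' whole grid mask is used.
#'
#' @param set_a,set_b [experiment_set()]s to contrast.
#' @param grid a [volume_grid()].
#' @param spec a [kernel_spec()].
#' @param n_perm number of permutations (default 25000).
#' @param p_thresh voxel-wise threshold on the permutation p (default 0.05).
#' @param min_extent minimum surviving cluster extent in voxels (default 5).
#' @param restrict_mask optional logical array restricting evaluation.
#' @param seed RNG seed.
#' @param connectivity cluster connectivity (6/18/26).
#' @return list with per-direction p maps (`p_a_gt_b`, `p_b_gt_a` as
#'   `stat_map`s), surviving cluster label maps and tables
#'   (`clusters_a_gt_b`, `clusters_b_gt_a`), the observed `diff` map and
#'   `n_permutations`.
#' @export
contrast_permutation <- function(set_a, set_b, grid, spec = kernel_spec(),
                                 n_perm = 25000, p_thresh = 0.05,
                                 min_extent = 5, restrict_mask = NULL,
                                 seed = 1, connectivity = 26) {
  if (!length(set_a) || !length(set_b)) stop("both sets must be non-empty")
  if (n_perm < 1 / p_thresh) {
    warning("n_perm below 1/p_thresh: permutation p values too coarse for ",
            "the requested threshold")
  }
  if (is.null(restrict_mask)) restrict_mask <- grid$mask
  vox <- which(restrict_mask & grid$mask)
  na <- length(set_a)
  nb <- length(set_b)
  pooled <- experiment_set(c(
    lapply(seq_len(na), function(i) {
      e <- set_a$experiments[[i]]
      e$experiment_id <- paste0("a_", i, "_", e$experiment_id)
      e
    }),
    lapply(seq_len(nb), function(i) {
      e <- set_b$experiments[[i]]
      e$experiment_id <- paste0("b_", i, "_", e$experiment_id)
      e
    })))
  L <- log_ma_matrix(pooled, grid, spec, vox)
  ale_from <- function(rows) 1 - exp(colSums(L[rows, , drop = FALSE]))
  obs <- ale_from(seq_len(na)) - ale_from(na + seq_len(nb))

  set.seed(seed)
  b_ge <- numeric(length(vox))
  b_le <- numeric(length(vox))
  block <- 200L
  done <- 0L
  while (done < n_perm) {
    nblk <- min(block, n_perm - done)
    sel <- matrix(0, nblk, na + nb)
    for (r in seq_len(nblk)) sel[r, sample.int(na + nb, na)] <- 1
    # group ALE for every permutation in the block via one matrix product
    sa <- 1 - exp(sel %*% L)
    sb <- 1 - exp((1 - sel) %*% L)
    d <- sa - sb
    b_ge <- b_ge + colSums(d >= rep(obs, each = nblk))
    b_le <- b_le + colSums(d <= rep(obs, each = nblk))
    done <- done + nblk
  }
  p_ab <- (b_ge + 1) / (n_perm + 1)
  p_ba <- (b_le + 1) / (n_perm + 1)

  make_p_map <- function(pv) {
    arr <- array(1, grid$shape)
    arr[vox] <- pv
    stat_map(grid, arr, "P")
  }
  diff_arr <- array(0, grid$shape)
  diff_arr[vox] <- obs
  sig_dir <- function(pv, sgn) {
    sig <- array(FALSE, grid$shape)
    sig[vox] <- pv < p_thresh
    surviving_components(sig, grid, min_extent, connectivity,
                         sgn * diff_arr)
  }
  ab <- sig_dir(p_ab, 1)
  ba <- sig_dir(p_ba, -1)
  list(p_a_gt_b = make_p_map(p_ab), p_b_gt_a = make_p_map(p_ba),
       label_a_gt_b = ab$label, clusters_a_gt_b = ab$clusters,
       label_b_gt_a = ba$label, clusters_b_gt_a = ba$clusters,
       diff = stat_map(grid, diff_arr, "Z"), n_permutations = n_perm,
       restrict_vox = vox)
}

#' Size-balanced meta-analytic contrast by subsampling
#'
#' When one experiment set is much larger than the other, its ALE analysis has
#' more power and the plain contrast is biased. This balancer repeats
#' [contrast_permutation()] on random size-matched subsets of the larger set;
#' a voxel survives iff it is significant (cluster-surviving) in at least
#' `agreement_fraction` of the subsamples. The consensus map is then subjected
#' to the same `min_extent` cluster filter.
#'
#' @param set_large,set_small [experiment_set()]s; `set_large` must be at
#'   least as large. `set_large` plays the role of group "a".
#' @param grid,spec,n_perm,p_thresh,min_extent,restrict_mask,seed,connectivity
#'   as in [contrast_permutation()].
#' @param n_subsamples number of random size-matched subsets (default 25).
#' @param agreement_fraction fraction of subsamples in which a voxel must
#'   survive (default 0.5).
#' @return list with per-direction consensus label maps and cluster tables,
#'   the per-direction agreement-fraction arrays (`vote_a_gt_b`,
#'   `vote_b_gt_a`), and `n_subsamples`.
#' @export
balanced_contrast <- function(set_large, set_small, grid,
                              spec = kernel_spec(), n_subsamples = 25,
                              agreement_fraction = 0.5, n_perm = 25000,
                              p_thresh = 0.05, min_extent = 5,
                              restrict_mask = NULL, seed = 1,
                              connectivity = 26) {
  if (length(set_large) < length(set_small)) {
    stop("set_large must be at least as large as set_small")
  }
  if (length(set_large) == length(set_small)) {
    message("sets are the same size; delegating to contrast_permutation()")
    res <- contrast_permutation(set_large, set_small, grid, spec, n_perm,
                                p_thresh, min_extent, restrict_mask, seed,
                                connectivity)
    return(c(res, list(n_subsamples = 1L)))
  }
  votes_ab <- array(0, grid$shape)
  votes_ba <- array(0, grid$shape)
  set.seed(seed)
  sub_idx <- replicate(n_subsamples,
                       sample.int(length(set_large), length(set_small)),
                       simplify = FALSE)
  for (s in seq_len(n_subsamples)) {
    res <- contrast_permutation(subset_experiments(set_large, sub_idx[[s]]),
                                set_small, grid, spec, n_perm, p_thresh,
                                min_extent, restrict_mask,
                                seed = seed + s, connectivity = connectivity)
    votes_ab <- votes_ab + (res$label_a_gt_b$data > 0)
    votes_ba <- votes_ba + (res$label_b_gt_a$data > 0)
  }
  votes_ab <- votes_ab / n_subsamples
  votes_ba <- votes_ba / n_subsamples
  cons <- function(v) {
    surviving_components(v >= agreement_fraction & grid$mask, grid,
                         min_extent, connectivity, v)
  }
  ab <- cons(votes_ab)
  ba <- cons(votes_ba)
  list(label_a_gt_b = ab$label, clusters_a_gt_b = ab$clusters,
       label_b_gt_a = ba$label, clusters_b_gt_a = ba$clusters,
       vote_a_gt_b = votes_ab, vote_b_gt_a = votes_ba,
       n_subsamples = n_subsamples)
}
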