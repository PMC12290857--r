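# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (enumeration / brute-force simulation) so they cannot
# share a defect with the implementation they check.

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, max_label) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(max_label + 1L)) {
      rec(c(labels, lab), max(max_label, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive-search maximum modularity for graphs small enough to enumerate.
exhaustive_max_modularity <- function(W, gamma = 1, negative = "asym") {
  B <- modularity_matrix(W, gamma, negative)
  best <- -Inf
  for (m in all_partitions(nrow(W))) {
    q <- sum(B[outer(m, m, "==")])
    if (q > best) best <- q
  }
  best
}

# Monte-Carlo oracle for the analytic ALE null: draw each experiment's MA
# value at an independent uniformly-random in-mask voxel and combine by the
# union rule.
mc_ale_null <- function(ma_maps, n_draws = 1e6, seed = 99) {
  set.seed(seed)
  acc <- rep(1, n_draws)
  for (m in ma_maps) {
    v <- masked_values(m)
    acc <- acc * (1 - sample(v, n_draws, replace = TRUE))
  }
  1 - acc
}

# Survival-function comparison between an analytic null and Monte-Carlo
# draws, evaluated on the analytic bin grid.
max_survival_gap <- function(null, draws) {
  xs <- null$value[null$prob > 0]
  mc_sf <- vapply(xs, function(x) mean(draws >= x - null$bin_width / 2), 1)
  max(abs(mc_sf - null_survival(null, xs)))
}

# Gaussian bump test map: max of isotropic bumps with given centres/heights,
# thresholded at `floor`.
bump_zmap <- function(grid, centers, heights, sd_mm = 6, floor = 0.05) {
  xyz <- grid_coords(grid, masked = FALSE)
  arr <- rep(0, nrow(xyz))
  for (i in seq_len(nrow(centers))) {
    arr <- pmax(arr, heights[i] *
                  exp(-rowSums(sweep(xyz, 2, centers[i, ])^2) /
                        (2 * sd_mm^2)))
  }
  arr[arr < floor] <- 0
  stat_map(grid, array(arr, grid$shape), "Z")
}

adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

table1_path <- function() {
  system.file("extdata", "impulsivity_nodes.tsv", package = "alenet")
}
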