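small_grid <- function() toy_brain_grid(c(24, 28, 24))

test_that("kernel width follows the two-variance-component form", {
  spec <- kernel_spec(sigma_template_mm = 3, sigma_subject_mm = 4)
  expect_equal(kernel_sd(4, spec), sqrt(9 + 16 / 4))
  expect_equal(kernel_sd(4, spec), 3.6056, tolerance = 1e-4)
  # sigma_subject -> 0 limit recovers the template term
  spec0 <- kernel_spec(sigma_template_mm = 3, sigma_subject_mm = 1e-9)
  expect_equal(kernel_sd(5, spec0), 3, tolerance = 1e-9)
  # strictly decreasing in n
  sds <- kernel_sd(1:100, spec)
  expect_true(all(diff(sds) < 0))
  expect_error(kernel_sd(0, spec), ">= 1")
})

test_that("MA maps peak at the focus, decay radially and combine by max", {
  g <- volume_grid(c(21, 21, 21), res = 2)  # unmasked grid
  spec <- kernel_spec()
  center <- vox_to_mm(g, c(11, 11, 11))[1, ]
  e1 <- experiment("s", "e1", "c", 20, center)
  m1 <- ma_map(e1, g, spec)
  expect_equal(which.max(m1$data), (11 - 1) * 441 + (11 - 1) * 21 + 11)
  # radially non-increasing along an axis
  prof <- m1$data[11:21, 11, 11]
  expect_true(all(diff(prof) <= 0))
  # discrete kernel mass per focus sums to 1 on an unmasked grid
  expect_equal(sum(m1$data), 1, tolerance = 1e-6)
  # two identical foci: identical map (non-additive max rule)
  e2 <- experiment("s", "e2", "c", 20, rbind(center, center))
  expect_equal(ma_map(e2, g, spec)$data, m1$data)
  # out-of-box focus is an error, out-of-mask focus only a warning
  expect_error(ma_map(experiment("s", "e3", "c", 20, c(999, 0, 0)), g, spec),
               "bounding box")
  gm <- small_grid()
  edge <- grid_coords(gm, masked = FALSE)[which(!gm$mask)[1], ]
  expect_warning(ma_map(experiment("s", "e4", "c", 20, edge), gm, spec),
                 "outside the mask")
})

test_that("the ALE union statistic matches its closed form and invariants", {
  g <- volume_grid(c(2, 2, 2))
  mk <- function(v) stat_map(g, array(v, c(2, 2, 2)), "MA")
  expect_equal(ale_map(list(mk(0.5), mk(0.5)))$data[1], 0.75)
  expect_equal(ale_map(list(mk(0.2), mk(0.3), mk(0.4)))$data[1], 0.664)
  # single experiment: identity
  expect_equal(ale_map(list(mk(0.31)))$data, mk(0.31)$data)
  # an all-zero MA map changes nothing
  expect_equal(ale_map(list(mk(0.2), mk(0.3), mk(0)))$data,
               ale_map(list(mk(0.2), mk(0.3)))$data)
  # monotone non-decreasing in each input
  expect_true(ale_map(list(mk(0.25), mk(0.3)))$data[1] >
                ale_map(list(mk(0.2), mk(0.3)))$data[1])
  g2 <- volume_grid(c(3, 3, 3))
  expect_error(ale_map(list(mk(0.2), stat_map(g2, array(0, c(3, 3, 3)),
                                              "MA"))), "share a grid")
})

test_that("the analytic null reproduces hand-computable cases", {
  g <- volume_grid(c(5, 5, 2))  # 50 voxels
  arr <- array(0, c(5, 5, 2))
  arr[1:10] <- 0.02  # fraction f = 0.2 at MA = 0.02
  null1 <- analytic_null(list(stat_map(g, arr, "MA")), bin_width = 1e-3)
  expect_equal(sum(null1$prob), 1, tolerance = 1e-9)
  expect_equal(null1$prob[null1$value == 0.02], 0.2)
  expect_equal(null1$prob[1], 0.8)
  # survival function is non-increasing
  expect_true(all(diff(null1$surv) <= 1e-12))
  # all-zero maps give a point mass at 0
  null0 <- analytic_null(list(stat_map(g, array(0, c(5, 5, 2)), "MA")))
  expect_equal(null0$prob[1], 1)
  expect_equal(null_survival(null0, 0.001), 1e-24)
})

test_that("two-experiment analytic null matches the Monte-Carlo pairing oracle", {
  g <- small_grid()
  corpus <- gen_foci_corpus(g, n_experiments = 2, noise_foci = 3, seed = 21)
  ma <- lapply(corpus$experiments, ma_map, grid = g)
  null <- analytic_null(ma)
  draws <- mc_ale_null(ma, n_draws = 1e6, seed = 5)
  expect_lt(max_survival_gap(null, draws), 0.005)
})

test_that("voxel thresholding flags planted convergence and honours bounds", {
  g <- small_grid()
  center <- c(0, 0, 0)
  corpus <- gen_foci_corpus(g, n_experiments = 3, foci_per_cluster = 2,
                            prob_hit = 1, noise_foci = 2, jitter_sd = 3,
                            seed = 8)
  ma <- lapply(corpus$experiments, ma_map, grid = g)
  ale <- ale_map(ma)
  null <- analytic_null(ma)
  thr <- voxel_threshold(ale, null, 0.001)
  cv <- nearest_voxel(g, center)
  peak_p <- thr$p$data[cv[1], cv[2], cv[3]]
  expect_lt(peak_p, 0.001)
  # background voxels (far corner of the mask) are clearly null
  far <- which(g$mask & ale$data == 0)
  expect_true(all(thr$p$data[far] > 0.1))
  # p_voxel = 1 retains every masked voxel
  thr_all <- voxel_threshold(ale, null, 1)
  expect_equal(sum(thr_all$label$data), sum(g$mask))
  # an ALE score below every nonzero null bin is not retained
  expect_equal(thr$label$data[far[1]], 0)
})

test_that("cluster-level FWE is deterministic and empty when nothing survives", {
  g <- small_grid()
  noise <- gen_foci_corpus(g, n_experiments = 3, cluster_centers = NULL,
                           noise_foci = 4, seed = 4)
  res <- cluster_fwe(noise, g, p_voxel = 1e-8, n_iter = 100, seed = 2)
  expect_equal(nrow(res$clusters), 0)
  planted <- gen_foci_corpus(g, n_experiments = 10, jitter_sd = 3, seed = 6)
  r1 <- cluster_fwe(planted, g, n_iter = 100, seed = 11)
  r2 <- cluster_fwe(planted, g, n_iter = 100, seed = 11)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$max_null_sizes, r2$max_null_sizes)
  expect_error(cluster_fwe(planted, g, n_iter = 50, seed = 1), ">= 100")
})
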