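test_that("resampling preserves constants, bounds and identity", {
  src <- volume_grid(c(11, 11, 11), res = 3)
  dst <- volume_grid(c(14, 14, 14), res = 2)
  const <- stat_map(src, array(7, src$shape), "density")
  out <- resample_map(const, dst)
  expect_true(all(abs(out$data - 7) < 1e-12))
  set.seed(2)
  rnd <- stat_map(src, array(stats::runif(prod(src$shape), 1, 9),
                             src$shape), "density")
  tri <- resample_map(rnd, dst)
  expect_gte(min(tri$data[dst$mask]), min(rnd$data))
  expect_lte(max(tri$data[dst$mask]), max(rnd$data))
  # identity resample is bitwise equal
  same <- resample_map(rnd, src)
  expect_identical(same$data, rnd$data)
  far <- volume_grid(c(5, 5, 5), affine = {
    a <- diag(c(2, 2, 2, 1))
    a[1:3, 4] <- c(1000, 1000, 1000)
    a
  })
  expect_error(resample_map(rnd, far), "do not overlap")
})

test_that("rescaling maps the range onto 0-100 idempotently", {
  g <- volume_grid(c(3, 3, 1))
  m <- stat_map(g, array(2:10, c(3, 3, 1)), "density")
  r <- rescale_map(m)
  expect_equal(r$data[g$mask][m$data[g$mask] == 6], 50)
  expect_equal(min(r$data[g$mask]), 0)
  expect_equal(max(r$data[g$mask]), 100)
  expect_equal(attr(r, "orig_min"), 2)
  expect_equal(rescale_map(r)$data, r$data)
  expect_error(rescale_map(stat_map(g, array(5, c(3, 3, 1)), "density")),
               "constant")
})

test_that("node density sampling averages the sphere and degrades gracefully", {
  net <- synthetic_network(n_nodes = 6, n_communities = 2)
  g <- net$grid
  const <- stat_map(g, array(3.3, g$shape), "density")
  prof <- sample_node_density(const, net$nodes)
  expect_equal(unname(prof), rep(3.3, 6))
  # planted coupling-1 map rank-orders with the metric
  metric <- c(2, 5, 1, 4, 6, 3)
  amap <- gen_annotation_map(g, net$nodes, metric, coupling = 1, seed = 1)
  p1 <- sample_node_density(amap, net$nodes)
  expect_equal(stats::cor(p1, metric, method = "spearman"), 1)
  # a radius beyond the mask extent averages the whole mask
  big <- sample_node_density(const, net$nodes[1, ], radius_mm = 1e4)
  expect_equal(unname(big), 3.3)
  far <- node_set(data.frame(region = "offgrid", hemisphere = "",
                             x = 1e4, y = 0, z = 0))
  expect_error(sample_node_density(const, far), "offgrid")
})

test_that("the two-dataset screen applies the effect-size and sign rules", {
  metric_a <- 1:10
  metric_b <- c(1:9, 11)
  profs <- list(mono = 1:10 * 2,
                rev = 10:1,
                weak = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  res <- screen_correlations(metric_a, metric_b, profs)
  expect_equal(res$rho_discovery[res$map == "mono"], 1)
  expect_equal(res$rho_discovery[res$map == "rev"], -1)
  expect_true(res$pass[res$map == "mono"])
  expect_true(res$pass[res$map == "rev"])  # strong in both, matching sign
  # |rho| = 0.29 in one dataset fails the screen
  set.seed(33)
  repeat {
    prof29 <- sample(1:10)
    r <- stats::cor(metric_a, prof29, method = "spearman")
    if (abs(r - 0.29) < 0.03) break
  }
  res29 <- screen_correlations(metric_a, prof29 * 1.0,
                               list(m = prof29 * 1.0), threshold = abs(r) + 0.001)
  expect_false(res29$pass)
  # monotone-transform invariance (Spearman property)
  res_t <- screen_correlations(metric_a, metric_b,
                               list(mono = exp(profs$mono / 3)))
  expect_equal(res_t$rho_discovery, 1)
  # one warning per dataset whose correlation is undefined
  expect_warning(expect_warning(
    res_c <- screen_correlations(metric_a, metric_b,
                                 list(flat = rep(1, 10))),
    "constant"), "constant")
  expect_false(res_c$pass)
})

test_that("random-network nulls respect the distance constraints exactly", {
  net <- synthetic_network()
  set.seed(5)
  metric <- stats::rnorm(21)
  amap <- gen_annotation_map(net$grid, net$nodes, metric, coupling = 0,
                             seed = 2)
  ens <- random_network_null(net$nodes, net$grid, map = amap,
                             metric = metric, n_networks = 150, seed = 12)
  ref <- ens$constraints$reference
  band <- ens$constraints$band
  for (xyz in ens$networks) {
    d <- as.numeric(stats::dist(xyz))
    expect_lte(abs(min(d) - ref["min"]), band)
    expect_lte(abs(mean(d) - ref["mean"]), band)
    expect_lte(abs(max(d) - ref["max"]), band)
  }
  # the empirical node set itself trivially satisfies its own constraints
  d_e <- as.numeric(stats::dist(node_coords(net$nodes)))
  expect_lte(abs(min(d_e) - ref["min"]), band)
  expect_lte(abs(max(d_e) - ref["max"]), band)
  # reproducible under a fixed seed
  ens2 <- random_network_null(net$nodes, net$grid, map = amap,
                              metric = metric, n_networks = 150, seed = 12)
  expect_identical(ens$networks, ens2$networks)
  expect_identical(ens$null_rho, ens2$null_rho)
})

test_that("the permutation test reads the null in the empirical direction", {
  null_rho <- seq(-0.5, 0.5, length.out = 1000)
  above <- null_test(0.6, null_rho)
  expect_lt(above$p, 0.001)
  expect_true(above$significant)
  mid <- null_test(0.0, null_rho)
  expect_equal(mid$p, 0.5, tolerance = 0.01)
  expect_false(mid$significant)
  neg <- null_test(-0.6, null_rho)
  expect_lt(neg$p, 0.001)
  expect_true(neg$significant)
  expect_equal(neg$direction, "negative")
})
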