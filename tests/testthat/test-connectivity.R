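test_that("framewise displacement follows the Power convention", {
  params <- rbind(c(0, 0, 0, 0, 0, 0),
                  c(1, 0, 0, 0, 0, 0),
                  c(1, 0.5, 0, 0.01, 0, 0))
  tr <- framewise_displacement(params)
  expect_equal(tr$fd, c(0, 1, 0.5 + 0.01 * 50))
  expect_equal(tr$mean_fd, mean(c(0, 1, 1)))
  expect_error(motion_trace(numeric(0)), "empty")
  expect_error(motion_trace(c(0.1, -0.2)), "non-negative")
})

test_that("the mean-FD filter keeps boundary subjects and drops movers", {
  traces <- list(motion_trace(rep(0.6, 10)),   # excluded at 0.5
                 motion_trace(rep(0.5, 10)),   # exactly at threshold: kept
                 motion_trace(rep(0.1, 10)))
  expect_equal(fd_filter(traces, 0.5), c(2L, 3L))
  expect_equal(fd_filter(traces[3], 0.5), 1L)          # identity when clean
  expect_equal(fd_filter(traces, 0.2), 3L)             # strict threshold
})

test_that("denoising removes confounds, trends and out-of-band power", {
  g <- volume_grid(c(3, 3, 3), res = 2)
  nt <- 300
  tr <- 1.4
  set.seed(7)
  gs <- stats::rnorm(nt)
  # every voxel equals the global-signal trace: residual numerically 0
  bold <- array(rep(gs, each = 27), c(3, 3, 3, nt))
  dn <- denoise(bold, g, confounds = cbind(gs = gs), tr_seconds = tr,
                smooth_fwhm = 0)
  expect_lt(max(abs(dn)), 1e-8)
  # pure 0.2 Hz sinusoid: amplitude cut to < 5 %
  tt <- (0:(nt - 1)) * tr
  s02 <- sin(2 * pi * 0.2 * tt)
  b2 <- array(rep(s02, each = 27), c(3, 3, 3, nt))
  dn2 <- denoise(b2, g, confounds = NULL, tr_seconds = tr, smooth_fwhm = 0)
  core <- 60:240  # avoid filter edge transients
  expect_lt(stats::sd(dn2[1, 1, 1, core]) / stats::sd(s02[core]), 0.05)
  # in-band 0.05 Hz signal largely passes
  s05 <- sin(2 * pi * 0.05 * tt)
  b5 <- array(rep(s05, each = 27), c(3, 3, 3, nt))
  dn5 <- denoise(b5, g, confounds = NULL, tr_seconds = tr, smooth_fwhm = 0)
  expect_gt(stats::sd(dn5[1, 1, 1, core]) / stats::sd(s05[core]), 0.7)
  # linear ramp is removed by detrending
  ramp <- array(rep(tt, each = 27), c(3, 3, 3, nt))
  dnr <- denoise(ramp, g, confounds = NULL, tr_seconds = tr, smooth_fwhm = 0)
  expect_lt(max(abs(dnr)), 1e-8)
  # collinear confounds are dropped with a warning
  expect_warning(denoise(bold, g, confounds = cbind(a = gs, b = gs),
                         tr_seconds = tr, smooth_fwhm = 0), "collinear")
  expect_error(denoise(bold, g, confounds = cbind(gs[1:10]),
                       tr_seconds = tr), "timepoint count")
})

test_that("sphere time series average the expected voxels", {
  g <- volume_grid(c(15, 15, 15), res = 2)
  nt <- 4
  set.seed(3)
  bold <- array(stats::rnorm(prod(g$shape) * nt), c(g$shape, nt))
  center <- vox_to_mm(g, c(8, 8, 8))[1, ]
  nodes <- node_set(data.frame(x = center[1], y = center[2], z = center[3]))
  ts <- sphere_timeseries(bold, g, nodes, radius_mm = 5)
  vox <- sphere_voxels(g, center, 5)
  expect_length(vox, 81)  # full 2 mm grid, node on a voxel centre
  M <- matrix(bold, prod(g$shape), nt)
  expect_equal(ts[1, ], colMeans(M[vox, ]), ignore_attr = TRUE)
  # radius 0.1 mm: single nearest voxel
  ts1 <- sphere_timeseries(bold, g, nodes, radius_mm = 0.1)
  expect_equal(ts1[1, ], bold[8, 8, 8, ], ignore_attr = TRUE)
  # constant volume gives a constant series
  ts_c <- sphere_timeseries(array(2.5, c(g$shape, nt)), g, nodes)
  expect_equal(unname(ts_c[1, ]), rep(2.5, nt))
  # empty sphere names the node
  far <- node_set(data.frame(region = "lost", hemisphere = "", x = 999,
                             y = 0, z = 0))
  expect_error(sphere_timeseries(bold, g, far), "lost")
})

test_that("FC matrices are Fisher-z averaged, symmetric and clipped", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  set.seed(11)
  ts <- matrix(stats::rnorm(5 * 200), 5, 200)
  fc <- fc_matrix(list(ts))
  expect_equal(fc, t(fc))
  expect_equal(diag(fc), rep(0, 5), ignore_attr = TRUE)
  expect_equal(fc[1, 2], atanh(stats::cor(ts[1, ], ts[2, ])))
  # r = 0 maps to z = 0 exactly (orthogonal series)
  orth <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(fc_matrix(list(orth))[1, 2], 0)
  # duplicated series stay finite through clipping
  dup <- rbind(ts[1, ], ts[1, ])
  expect_true(is.finite(fc_matrix(list(dup))[1, 2]))
  expect_gt(fc_matrix(list(dup))[1, 2], 8)
  # averaging across subjects is element-wise
  ts2 <- matrix(stats::rnorm(5 * 200), 5, 200)
  fc_mean <- fc_matrix(list(ts, ts2))
  expect_equal(fc_mean, (fc_matrix(list(ts)) + fc_matrix(list(ts2))) / 2)
  expect_warning(fc_matrix(list(rbind(rep(1, 10), stats::rnorm(10)))),
                 "zero-variance")
})

test_that("seed-to-voxel maps are coherent with the generating structure", {
  net <- synthetic_network(n_nodes = 8, n_communities = 2, spacing_mm = 14,
                           margin_mm = 8)
  sim <- gen_bold(net$grid, net$nodes, net$membership, within_r = 0.6,
                  between_r = 0, n_timepoints = 150, n_subjects = 2,
                  noise_sd = 0.3, seed = 17)
  bolds <- lapply(sim$subjects, `[[`, "bold")
  sms <- seed_to_voxel(bolds, net$grid, net$nodes)
  expect_equal(dim(sms$maps), c(8, sum(net$grid$mask)))
  # voxels inside the seed sphere correlate strongly with the seed
  vox1 <- sphere_voxels(net$grid, node_coords(net$nodes)[1, ], 5)
  cols <- match(vox1, sms$vox)
  expect_gt(min(sms$maps[1, cols]), 1)  # Fisher z of a high correlation
  # single subject: group map equals that subject's map
  one <- seed_to_voxel(bolds[1], net$grid, net$nodes)
  again <- seed_to_voxel(bolds[1], net$grid, net$nodes)
  expect_equal(one$maps, again$maps)
  # within-community seed maps are more similar than between
  S <- similarity_matrix(sms)
  same <- outer(net$membership, net$membership, "==") & upper.tri(S)
  diff <- outer(net$membership, net$membership, "!=") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})
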