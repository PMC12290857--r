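two_triangles <- function() {
  W <- matrix(0, 6, 6)
  for (blk in list(1:3, 4:6)) {
    W[blk, blk] <- 1
  }
  diag(W) <- 0
  W
}

test_that("Louvain attains the exhaustive-search modularity optimum", {
  W <- two_triangles()
  p <- louvain_finetuned(W, seed = 1)
  expect_equal(p$Q, 0.5)
  expect_equal(max(p$membership), 2)
  expect_equal(p$Q, exhaustive_max_modularity(W))
  # random small graphs, signed and unsigned
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    A <- matrix(stats::rnorm(n^2, sd = 0.5), n, n)
    A <- (A + t(A)) / 2
    if (rep <= 3) A <- abs(A)
    diag(A) <- 0
    best <- exhaustive_max_modularity(A)
    got <- louvain_finetuned(A, seed = rep)$Q
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("Louvain handles degenerate graphs and is seed-deterministic", {
  Wfull <- matrix(1, 5, 5)
  diag(Wfull) <- 0
  expect_equal(max(louvain_finetuned(Wfull, seed = 3)$membership), 1)
  z <- louvain_finetuned(matrix(0, 4, 4))
  expect_equal(z$membership, rep(1L, 4))
  expect_equal(z$Q, 0)
  W <- two_triangles()
  expect_identical(louvain_finetuned(W, seed = 5),
                   louvain_finetuned(W, seed = 5))
  expect_error(louvain_finetuned(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("Louvain agrees with an independent implementation on positive graphs", {
  skip_if_not_installed("igraph")
  set.seed(9)
  # planted two-block weighted graph
  W <- matrix(stats::runif(100, 0, 0.2), 10, 10)
  W[1:5, 1:5] <- W[1:5, 1:5] + 1
  W[6:10, 6:10] <- W[6:10, 6:10] + 1
  W <- (W + t(W)) / 2
  diag(W) <- 0
  ours <- louvain_finetuned(W, seed = 2, negative = "ignore")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  theirs <- igraph::cluster_louvain(g)
  expect_equal(adjusted_rand(ours$membership, igraph::membership(theirs)), 1)
  expect_equal(ours$Q, igraph::modularity(g, ours$membership,
                                          weights = igraph::E(g)$weight),
               tolerance = 1e-9)
})

test_that("consensus detection yields agreement in {0,1} on a deterministic graph", {
  W <- two_triangles()
  cc <- consensus_communities(W, n_reps = 25, seed = 4)
  expect_true(all(cc$agreement %in% c(0, 1)))
  expect_equal(cc$frequency, 1)
  expect_equal(diag(cc$agreement), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cc$agreement, t(cc$agreement))
  expect_equal(adjusted_rand(cc$partition$membership, rep(1:2, each = 3)), 1)
  # the iterative consensus option agrees here
  cc2 <- consensus_communities(W, n_reps = 25, seed = 4,
                               method = "iterative")
  expect_equal(adjusted_rand(cc2$partition$membership, rep(1:2, each = 3)), 1)
})

test_that("participation coefficient matches closed-form splits", {
  # star node 1 split evenly across k modules
  mk <- function(k) {
    W <- matrix(0, k + 1, k + 1)
    W[1, 2:(k + 1)] <- 1
    W <- W + t(W)
    list(W = W, m = c(1, seq_len(k)))
  }
  for (k in c(2, 4)) {
    g <- mk(k)
    expect_equal(participation_coefficient(g$W, g$m)[1], 1 - k * (1 / k)^2)
  }
  # all strength within the own module: P = 0
  W <- two_triangles()
  expect_equal(participation_coefficient(W, rep(1:2, each = 3)),
               rep(0, 6))
  expect_warning(
    P0 <- participation_coefficient(rbind(c(0, 0), c(0, 0)), c(1, 2)),
    "isolated")
  expect_equal(P0, c(0, 0))
})

test_that("within-module degree z-score standardises within communities", {
  W <- two_triangles()
  # regular within-module graph: z = 0 everywhere
  expect_equal(within_module_zscore(W, rep(1:2, each = 3)), rep(0, 6))
  # a hub with doubled within-strength has its module's maximum z
  W2 <- matrix(0, 5, 5)
  W2[1, 2:5] <- 2
  W2[2, 3] <- W2[3, 4] <- W2[4, 5] <- W2[5, 2] <- 1
  W2 <- pmax(W2, t(W2))
  z <- within_module_zscore(W2, rep(1, 5))
  expect_equal(which.max(z), 1L)
  # permutation equivariance
  perm <- c(3, 1, 4, 5, 2)
  z_perm <- within_module_zscore(W2[perm, perm], rep(1, 5))
  expect_equal(z_perm, z[perm])
  expect_warning(within_module_zscore(two_triangles(), c(1, 1, 1, 2, 2, 3)),
                 "singleton")
})

test_that("hand-computed node metrics on a two-community toy graph", {
  # nodes 1-3 a triangle, nodes 4-5 a dyad, plus one bridge 3-4
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[1, 3] <- W[2, 3] <- 1
  W[4, 5] <- 1
  W[3, 4] <- 1
  W <- pmax(W, t(W))
  m <- c(1, 1, 1, 2, 2)
  P <- participation_coefficient(W, m)
  # node 3: strength 3, 2 within / 1 across: P = 1 - (2/3)^2 - (1/3)^2
  expect_equal(P[3], 1 - (2 / 3)^2 - (1 / 3)^2)
  # node 4: strength 2, half across: P = 0.5
  expect_equal(P[4], 0.5)
  expect_equal(P[c(1, 2, 5)], rep(0, 3))
  z <- within_module_zscore(W, m)
  # module 1 within-strengths (2,2,2): sd 0, z = 0; module 2 (1,1): z = 0
  expect_equal(z, rep(0, 5))
})

test_that("similarity matrices follow correlation identities", {
  set.seed(8)
  base <- matrix(stats::rnorm(4 * 50), 4, 50)
  M <- rbind(base[1, ], base[1, ], -base[1, ], base[2, ])
  S <- similarity_matrix(M)
  expect_equal(S[1, 2], 1)
  expect_equal(S[1, 3], -1)
  expect_equal(S, t(S))
  M21 <- matrix(stats::rnorm(21 * 60), 21, 60)
  expect_equal(dim(similarity_matrix(M21)), c(21, 21))
  expect_warning(similarity_matrix(rbind(rep(1, 10), stats::rnorm(10))),
                 "constant")
})

test_that("gradient decomposition separates planted blocks and stays stable", {
  S <- block_covariance(rep(1:2, each = 6), 0.8, 0.1)
  gr <- gradient_decomposition(S, sparsity = 0.2, k = 3)
  s1 <- sign(gr$loadings[, 1])
  expect_equal(length(unique(s1[1:6])), 1)
  expect_equal(length(unique(s1[7:12])), 1)
  expect_true(s1[1] != s1[7])
  # eigen-decomposition oracle: first PC of the centred sparsified matrix
  expect_true(all(diff(gr$evf) <= 1e-12))
  # components mutually orthogonal
  cp <- crossprod(gr$loadings)
  expect_equal(cp[upper.tri(cp)], rep(0, 3), tolerance = 1e-9)
  # block assignment by sign is unchanged across sparsity levels
  for (sp in c(0.3, 0.4)) {
    s <- sign(gradient_decomposition(S, sparsity = sp)$loadings[, 1])
    expect_equal(s, s1)
  }
  # diffusion-map variant also separates the blocks (by value)
  gd <- gradient_decomposition(S, method = "diffusion", k = 2)
  expect_gt(abs(mean(gd$loadings[1:6, 1]) - mean(gd$loadings[7:12, 1])), 0.01)
  # identity-like similarity: near-uniform explained variance
  gi <- gradient_decomposition(diag(12), sparsity = 0.2, k = 3)
  expect_lt(diff(range(gi$evf)), 0.05)
  expect_warning(gradient_decomposition(S, k = 50), "truncating")
})
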