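#' Modularity matrix of a (possibly signed) weighted graph
#'
#' Returns the matrix `B` such that the modularity of a partition `M` is
#' `Q = sum(B[i, j] : M[i] == M[j])`. Positive and negative weights are
#' handled with the asymmetric extension: the positive-part modularity is
#' normalised by the positive strength `s+`, the negative part contributes
#' with the reduced weight `1 / (s+ + s-)`, so sparse negative edges cannot
#' dominate the partition.
#'
#' @param W symmetric weight matrix (zero diagonal recommended).
#' @param gamma resolution parameter (default 1).
#' @param negative `"asym"` (default) for the asymmetric signed extension or
#'   `"ignore"` to use positive weights only.
#' @export
modularity_matrix <- function(W, gamma = 1, negative = c("asym", "ignore")) {
  negative <- match.arg(negative)
  W <- as.matrix(W)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10))) {
    stop("W must be symmetric")
  }
  W0 <- pmax(W, 0)
  W1 <- -pmin(W, 0)
  s0 <- sum(W0)
  s1 <- sum(W1)
  B <- matrix(0, nrow(W), ncol(W))
  if (s0 > 0) {
    B <- (W0 - gamma * outer(rowSums(W0), colSums(W0)) / s0) / s0
  }
  if (negative == "asym" && s1 > 0) {
    B <- B - (W1 - gamma * outer(rowSums(W1), colSums(W1)) / s1) / (s0 + s1)
  }
  (B + t(B)) / 2
}

modularity_value <- function(B, membership) {
  sum(B[outer(membership, membership, "==")])
}

# One pass of greedy local moving on modularity matrix B, visiting nodes in
# random order until no single-node move increases Q.
local_move <- function(B, membership) {
  n <- nrow(B)
  M <- membership
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      w <- as.numeric(rowsum(B[i, ], M))
      comms <- as.integer(rownames(rowsum(B[i, ], M)))
      names(w) <- comms
      ci <- as.character(M[i])
      w_home <- w[ci] - B[i, i]
      gain <- w - w_home
      gain[ci] <- 0
      best <- which.max(gain)
      if (gain[best] > 1e-12) {
        M[i] <- as.integer(names(w)[best])
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  match(M, unique(M))
}

# Full Louvain on a modularity matrix: node-level local moving (optionally
# from an initial partition), then repeated community aggregation with local
# moving at the coarse level until the partition stops coarsening.
louvain_on_B <- function(B, init = NULL) {
  n <- nrow(B)
  M <- if (is.null(init)) seq_len(n) else match(init, unique(init))
  M <- local_move(B, M)
  repeat {
    B_agg <- rowsum_cross(B, M)
    M_agg <- local_move(B_agg, seq_len(max(M)))
    M2 <- match(M_agg[M], unique(M_agg[M]))
    if (max(M2) == max(M)) {
      M <- M2
      break
    }
    M <- M2
  }
  M
}

# Aggregate B over community blocks: result[c1, c2] = sum of B within block.
rowsum_cross <- function(B, M) {
  f <- factor(M, levels = sort(unique(M)))
  t(rowsum(t(rowsum(B, f)), f))
}

#' Louvain community detection with fine-tuning
#'
#' One Louvain run (greedy local moving plus aggregation on the modularity
#' matrix), followed by iterative refinement: the algorithm is re-run with
#' the current partition as initialisation until the modularity Q stops
#' increasing (tolerance 1e-10).
#'
#' @param W symmetric weight matrix (e.g. a Fisher-z FC matrix; negative
#'   entries allowed, see [modularity_matrix()]).
#' @param gamma resolution parameter.
#' @param seed RNG seed controlling the stochastic node visiting order.
#' @param negative negative-weight handling, see [modularity_matrix()].
#' @return A `partition`: list with `membership` (contiguous labels from 1,
#'   in order of first appearance) and modularity `Q`.
#' @export
louvain_finetuned <- function(W, gamma = 1, seed = 1,
                              negative = c("asym", "ignore")) {
  negative <- match.arg(negative)
  B <- modularity_matrix(W, gamma, negative)
  n <- nrow(B)
  if (all(B == 0)) {
    return(structure(list(membership = rep(1L, n), Q = 0),
                     class = "partition"))
  }
  set.seed(seed)
  M <- louvain_on_B(B)
  # local moving on the original nodes with the coarse partition as start
  M <- local_move(B, M)
  Q0 <- modularity_value(B, M)
  repeat {
    M2 <- local_move(B, louvain_on_B(B, init = M))
    Q1 <- modularity_value(B, M2)
    if (Q1 > Q0 + 1e-10) {
      M <- M2
      Q0 <- Q1
    } else {
      break
    }
  }
  structure(list(membership = match(M, unique(M)), Q = Q0),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition: %d communities over %d nodes, Q = %.4f>\n",
              max(x$membership), length(x$membership), x$Q))
  invisible(x)
}

canonical_labels <- function(membership) {
  match(membership, unique(membership))
}

#' Consensus community detection
#'
#' Repeats [louvain_finetuned()] `n_reps` times (the node visiting order is
#' the only randomness) and records (i) the agreement matrix -- the fraction
#' of runs placing each node pair in the same community -- and (ii) the modal
#' partition: the most frequent label-invariant solution, with its frequency.
#'
#' @inheritParams louvain_finetuned
#' @param n_reps number of repetitions (default 1000).
#' @param method `"modal"` (default) returns the most frequent solution;
#'   `"iterative"` re-clusters the agreement matrix (centred at `tau`) with a
#'   final Louvain pass.
#' @param tau agreement offset for `method = "iterative"`.
#' @return list with `partition` (the consensus `partition`), `agreement`
#'   (symmetric matrix with unit diagonal) and `frequency` (modal solution
#'   frequency; `NA` for the iterative method).
#' @export
consensus_communities <- function(W, n_reps = 1000, gamma = 1, seed = 1,
                                  negative = c("asym", "ignore"),
                                  method = c("modal", "iterative"),
                                  tau = 0.5) {
  stopifnot(n_reps >= 2)
  negative <- match.arg(negative)
  method <- match.arg(method)
  n <- nrow(W)
  agree <- matrix(0, n, n)
  keys <- character(n_reps)
  sols <- vector("list", n_reps)
  Qs <- numeric(n_reps)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  for (r in seq_len(n_reps)) {
    part <- louvain_finetuned(W, gamma, seed = rep_seeds[r],
                              negative = negative)
    m <- canonical_labels(part$membership)
    agree <- agree + outer(m, m, "==")
    keys[r] <- paste(m, collapse = ",")
    sols[[r]] <- m
    Qs[r] <- part$Q
  }
  agree <- agree / n_reps
  diag(agree) <- 1
  dimnames(agree) <- dimnames(W)
  if (method == "modal") {
    tab <- sort(table(keys), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    modal_key <- sort(top)[1]  # deterministic tie-break
    idx <- which(keys == modal_key)[1]
    part <- structure(list(membership = sols[[idx]], Q = Qs[idx]),
                      class = "partition")
    freq <- as.numeric(max(tab)) / n_reps
  } else {
    part <- louvain_finetuned(agree - tau, gamma, seed = seed,
                              negative = "ignore")
    part$Q <- modularity_value(modularity_matrix(W, gamma, negative),
                               part$membership)
    freq <- NA_real_
  }
  list(partition = part, agreement = agree, frequency = freq)
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_c (s_ic / s_i)^2`, where `s_ic` is node i's strength into
#' community c and `s_i` its total strength, computed on the positive (or
#' negative) part of the weights. High values mark nodes whose connections
#' are distributed across communities (integrators); `P = 0` marks a node
#' with all strength inside one module.
#'
#' @param W symmetric weight matrix.
#' @param membership community label per node.
#' @param sign `"positive"` (default) or `"negative"` weight part.
#' @return numeric vector of per-node participation coefficients in [0, 1).
#' @export
participation_coefficient <- function(W, membership,
                                      sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  Wp <- if (sign == "positive") pmax(W, 0) else -pmin(W, 0)
  diag(Wp) <- 0
  n <- nrow(Wp)
  stopifnot(length(membership) == n)
  s <- rowSums(Wp)
  f <- factor(membership, levels = sort(unique(membership)))
  s_ic <- t(rowsum(t(Wp), f))  # n x n_comm
  P <- numeric(n)
  ok <- s > 0
  if (any(!ok)) warning("isolated node(s) with zero strength: P set to 0")
  P[ok] <- 1 - rowSums((s_ic[ok, , drop = FALSE] / s[ok])^2)
  P
}

#' Within-module degree z-score
#'
#' Standardised within-community strength: `z_i = (k_i - mean_c) / sd_c`,
#' where `k_i` is node i's summed weight to other members of its own
#' community and the mean/sd are taken over that community's nodes. Singleton
#' modules and zero-spread modules get `z = 0` (documented convention).
#'
#' @param W symmetric weight matrix.
#' @param membership community label per node.
#' @return numeric vector of per-node z-scores.
#' @export
within_module_zscore <- function(W, membership) {
  W <- as.matrix(W)
  diag(W) <- 0
  n <- nrow(W)
  stopifnot(length(membership) == n)
  z <- numeric(n)
  for (c in unique(membership)) {
    idx <- which(membership == c)
    if (length(idx) == 1L) {
      warning("singleton module ", c, ": z set to 0")
      next
    }
    k <- rowSums(W[idx, idx, drop = FALSE])
    s <- stats::sd(k)
    if (s > 0) z[idx] <- (k - mean(k)) / s
  }
  z
}

#' Node-by-node similarity of seed-to-voxel maps
#'
#' Pearson correlation between the vectorised grey-matter seed maps of every
#' node pair.
#'
#' @param seed_maps a `seed_map_set` from [seed_to_voxel()], or a bare
#'   nodes x voxels matrix.
#' @return symmetric nodes x nodes correlation matrix (unit diagonal).
#' @export
similarity_matrix <- function(seed_maps) {
  M <- if (inherits(seed_maps, "seed_map_set")) seed_maps$maps else
    as.matrix(seed_maps)
  stopifnot(nrow(M) >= 2)
  sds <- apply(M, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant seed map(s): ", paste(which(sds == 0), collapse = ", "),
            "; similarity undefined (NA)")
  }
  S <- suppressWarnings(stats::cor(t(M)))
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

sparsify_rows <- function(S, sparsity) {
  n <- nrow(S)
  keep_n <- max(1L, ceiling(sparsity * (n - 1)))
  out <- S
  for (i in seq_len(n)) {
    off <- setdiff(seq_len(n), i)
    cut <- sort(S[i, off], decreasing = TRUE)[keep_n]
    drop <- off[S[i, off] < cut]
    out[i, drop] <- 0
  }
  out
}

#' Gradient decomposition of a similarity matrix
#'
#' Identifies the principal axes of variation across nodes' connectivity
#' profiles. Each row of the similarity matrix is sparsified to its top
#' `sparsity` fraction of off-diagonal entries (the rest set to 0), then
#' decomposed by PCA (rows as observations) or by diffusion-map embedding
#' with anisotropic-diffusion parameter `alpha`. Components are sign-aligned
#' so the loading of the first node is non-negative.
#'
#' @param S symmetric similarity matrix.
#' @param sparsity fraction of off-diagonal entries *retained* per row
#'   (default 0.20 = keep the top 20 percent).
#' @param method `"pca"` (default) or `"diffusion"`.
#' @param alpha anisotropic diffusion parameter for the diffusion map.
#' @param k number of components (truncated to the available rank with a
#'   warning).
#' @return A `gradient_set`: list with `loadings` (nodes x k), `evf`
#'   (explained-variance fractions for PCA; normalised eigenvalue fractions
#'   for the diffusion map; non-increasing), `method`, `sparsity`, `alpha`.
#' @export
gradient_decomposition <- function(S, sparsity = 0.20,
                                   method = c("pca", "diffusion"),
                                   alpha = 0.05, k = 3) {
  method <- match.arg(method)
  S <- as.matrix(S)
  stopifnot(isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
  n <- nrow(S)
  Ssp <- sparsify_rows(S, sparsity)
  if (method == "pca") {
    pc <- stats::prcomp(Ssp, center = TRUE, scale. = FALSE)
    avail <- sum(pc$sdev > 1e-12)
    if (k > avail) {
      warning("k = ", k, " exceeds the available rank ", avail,
              "; truncating")
      k <- avail
    }
    load <- pc$x[, seq_len(k), drop = FALSE]
    evf <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  } else {
    A <- pmax((Ssp + t(Ssp)) / 2, 0)
    d <- rowSums(A)
    if (any(d == 0)) stop("diffusion embedding needs every node connected")
    L <- A / outer(d^alpha, d^alpha)
    d2 <- rowSums(L)
    Ms <- L / sqrt(outer(d2, d2))  # symmetric conjugate of the random walk
    eig <- eigen(Ms, symmetric = TRUE)
    psi <- eig$vectors / sqrt(d2)
    lam <- eig$values
    avail <- min(n - 1L, sum(abs(lam) > 1e-12) - 1L)
    if (k > avail) {
      warning("k = ", k, " exceeds the available rank ", avail,
              "; truncating")
      k <- avail
    }
    sel <- 1 + seq_len(k)  # drop the trivial constant eigenvector
    load <- sweep(psi[, sel, drop = FALSE], 2, lam[sel], "*")
    evf <- (lam[sel] / sum(abs(lam[-1])))
  }
  for (j in seq_len(ncol(load))) {
    nz <- which(abs(load[, j]) > 1e-12)
    if (length(nz) && load[nz[1], j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- rownames(S)
  structure(list(loadings = load, evf = evf, method = method,
                 sparsity = sparsity, alpha = alpha),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set: %d components (%s), evf %s>\n",
              ncol(x$loadings), x$method,
              paste(signif(x$evf, 3), collapse = ", ")))
  invisible(x)
}
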