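# Independent oracles used across the suite: deliberately naive
# implementations (double loops, exhaustive enumeration) kept separate from
# the production code paths they check.

# Phase record wrapper around a raw samples-x-nodes matrix.
fake_record <- function(ph, dt_eff = 0.1) {
  structure(list(times = seq_len(nrow(ph)) * dt_eff, phases = ph,
                 unwrapped = NULL, init = NULL, n_nodes = ncol(ph),
                 K = NA_real_, D = NA_real_, dt = dt_eff, stride = 1L,
                 dt_eff = dt_eff, t_transient = 0, t_measure = NA_real_,
                 seed = NULL),
            class = "phase_record")
}

# Coherence matrix from a raw symmetric weight matrix.
fake_wns <- function(W) {
  W <- (W + t(W)) / 2
  netsync:::new_coherence_matrix(W, provenance = "fixture")
}

# Per-edge double-loop Kuramoto drift.
drift_oracle <- function(theta, omega, K, net) {
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  n <- length(theta)
  f <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) if (A[i, j] == 1) acc <- acc + sin(theta[j] - theta[i])
    f[i] <- omega[i] + K * acc
  }
  f
}

# Decode a Pruefer sequence into the edge matrix of the labelled tree.
prufer_to_tree <- function(s, n) {
  d <- tabulate(s, n) + 1
  edges <- matrix(0L, n - 1, 2)
  for (i in seq_along(s)) {
    leaf <- min(which(d == 1))
    edges[i, ] <- c(leaf, s[i])
    d[leaf] <- 0L
    d[s[i]] <- d[s[i]] - 1L
  }
  edges[n - 1, ] <- which(d == 1)
  edges
}

# Maximum spanning-tree weight by exhaustive enumeration over all n^(n-2)
# labelled trees (Cayley).
max_tree_weight_oracle <- function(W) {
  n <- nrow(W)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_to_tree(seqs[r, ], n)
    best <- max(best, sum(W[e]))
  }
  best
}

# ROC points by an explicit per-threshold loop (threshold at every distinct
# weight; prediction is weight >= threshold).
roc_oracle <- function(w, lab) {
  th <- sort(unique(w), decreasing = TRUE)
  pts <- t(vapply(th, function(t0) {
    pred <- w >= t0
    c(fpr = sum(pred & !lab) / sum(!lab), tpr = sum(pred & lab) / sum(lab))
  }, c(fpr = 0, tpr = 0)))
  rbind(c(fpr = 0, tpr = 0), pts)
}

# AUC as the probability that a random positive outweighs a random negative,
# ties counted one half, by exhaustive pair comparison.
auc_pair_oracle <- function(w, lab) {
  wp <- w[lab]; wn <- w[!lab]
  cmp <- outer(wp, wn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small simulated system shared by several tests.
tiny_ba_record <- function(n = 32, K = 0.05, seed = 42, t_measure = 30) {
  g <- generate_ba(n, 2, seed = seed)
  list(net = g,
       rec = simulate_phases(g, K = K, t_transient = 10,
                             t_measure = t_measure, seed = seed + 1))
}
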