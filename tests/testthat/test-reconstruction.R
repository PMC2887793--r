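# A 6-node toy with 8 physical links (15 pairs total) whose weights are set
# so thresholding at 0.5 yields the canonical confusion counts
# TP = 5, TN = 5, FP = 2, FN = 3.
toy_instance <- function() {
  n <- 6
  pairs <- netsync:::link_pairs(n)
  phys <- c(1, 2, 3, 4, 5, 6, 7, 8) # first 8 link indices are physical
  lab <- seq_len(nrow(pairs)) %in% phys
  w <- numeric(nrow(pairs))
  w[lab] <- c(0.9, 0.85, 0.8, 0.75, 0.7, 0.3, 0.25, 0.2) # 5 above 0.5
  w[!lab] <- c(0.65, 0.6, 0.15, 0.12, 0.1, 0.08, 0.05)   # 2 above 0.5
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- w
  W <- W + t(W)
  truth <- igraph::make_empty_graph(n, directed = FALSE)
  truth <- igraph::add_edges(truth, rbind(pairs$node_a[lab], pairs$node_b[lab]))
  list(wns = fake_wns(W), truth = truth, w = w, lab = lab)
}

test_that("confusion counts: trivial thresholds and the worked 15-pair example", {
  toy <- toy_instance()
  below <- classify_links(toy$wns, -1, toy$truth)
  expect_identical(below$tp + below$fp, 15L)
  expect_identical(below$tn + below$fn, 0L)
  above <- classify_links(toy$wns, 1, toy$truth)
  expect_identical(above$tn + above$fn, 15L)
  expect_identical(above$tp + above$fp, 0L)
  cc <- classify_links(toy$wns, 0.5, toy$truth)
  expect_identical(unlist(cc[c("tp", "tn", "fp", "fn")]),
                   c(tp = 5L, tn = 5L, fp = 2L, fn = 3L))
  expect_equal(cc$fpr, 2 / 7)
  expect_equal(cc$tpr, 5 / 8)
})

test_that("ROC sweep equals the brute-force per-threshold loop, ties included", {
  set.seed(6)
  for (i in 1:5) {
    n <- 5
    w <- sample(round(runif(10), 2)) # duplicates force tie groups
    lab <- as.logical(rbinom(10, 1, 0.5))
    if (!any(lab) || all(lab)) next
    W <- matrix(0, n, n); W[upper.tri(W)] <- w; W <- W + t(W)
    truth <- igraph::make_empty_graph(n, directed = FALSE)
    pairs <- netsync:::link_pairs(n)
    truth <- igraph::add_edges(truth,
                               rbind(pairs$node_a[lab], pairs$node_b[lab]))
    roc <- roc_curve(fake_wns(W), truth)
    oracle <- roc_oracle(w, lab)
    expect_equal(cbind(fpr = roc$fpr, tpr = roc$tpr), unname(oracle),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
    # trapezoidal AUC equals the pair-ordering probability with half ties
    expect_equal(auc(roc), auc_pair_oracle(w, lab), tolerance = 1e-12)
  }
})

test_that("AUC endpoints: perfect separation, diagonal baseline, monotone invariance", {
  toy <- toy_instance()
  # indicator weights reconstruct perfectly
  n <- 6; pairs <- netsync:::link_pairs(n)
  W <- matrix(0, n, n); W[upper.tri(W)] <- as.numeric(toy$lab); W <- W + t(W)
  perfect <- roc_curve(fake_wns(W), toy$truth)
  expect_equal(auc(perfect), 1)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  # truth-independent constant weights: the curve is the diagonal
  Wc <- matrix(0.4, n, n)
  expect_equal(auc(roc_curve(fake_wns(Wc), toy$truth)), 0.5)
  # AUC is invariant under strictly monotone weight transforms
  r1 <- auc(roc_curve(toy$wns, toy$truth))
  W3 <- unclass(toy$wns)^3
  expect_equal(auc(roc_curve(fake_wns(W3), toy$truth)), r1, tolerance = 1e-12)
})

test_that("random weights score at the 0.5 baseline", {
  set.seed(7)
  g <- generate_ba(100, 2, seed = 71)
  vals <- replicate(20, {
    W <- matrix(0, 100, 100); W[upper.tri(W)] <- runif(4950); W <- W + t(W)
    auc(roc_curve(fake_wns(W), g))
  })
  expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("top-L truncation is a prefix of the full sweep", {
  toy <- toy_instance()
  full <- roc_curve(toy$wns, toy$truth)
  same <- top_l_roc(toy$wns, toy$truth, 15)
  expect_equal(tibble::as_tibble(same), tibble::as_tibble(full),
               ignore_attr = TRUE)
  one <- top_l_roc(toy$wns, toy$truth, 1)
  expect_identical(nrow(one), 2L) # (0,0) plus the heaviest link
  expect_equal(one$tpr[2] * attr(one, "n_pos") +
                 one$fpr[2] * attr(one, "n_neg"), 1)
  l5 <- top_l_roc(toy$wns, toy$truth, 5)
  expect_equal(tibble::as_tibble(l5),
               tibble::as_tibble(full)[seq_len(nrow(l5)), ],
               ignore_attr = TRUE)
  expect_error(top_l_roc(toy$wns, toy$truth, 16), "range")
  expect_error(top_l_roc(toy$wns, toy$truth, 0), "range")
})

test_that("bimodal threshold finds the antimode between well-separated modes", {
  set.seed(8)
  n <- 40 # 780 pairs
  w <- c(rnorm(580, 0.05, 0.015), rnorm(200, 0.4, 0.03))
  w <- pmin(pmax(w, 0), 1)
  W <- matrix(0, n, n); W[upper.tri(W)] <- w; W <- W + t(W)
  est <- bimodal_threshold(fake_wns(W))
  expect_true(est$bimodal)
  expect_gt(est$threshold, est$mode_lo)
  expect_lt(est$threshold, est$mode_hi)
  expect_gt(est$threshold, 0.1)
  expect_lt(est$threshold, 0.35)
  expect_gt(est$separation_quality, 0.5)
  # a single bump is flagged unimodal with the median fallback
  w1 <- rnorm(780, 0.3, 0.02)
  W1 <- matrix(0, n, n); W1[upper.tri(W1)] <- w1; W1 <- W1 + t(W1)
  est1 <- bimodal_threshold(fake_wns(W1))
  expect_false(est1$bimodal)
  expect_identical(est1$separation_quality, 0)
  expect_equal(est1$threshold, median(w1))
})

test_that("thresholding round trip: indicator WNS reconstructs the truth exactly", {
  toy <- toy_instance()
  n <- 6; pairs <- netsync:::link_pairs(n)
  W <- matrix(0, n, n); W[upper.tri(W)] <- as.numeric(toy$lab); W <- W + t(W)
  got <- reconstruct(fake_wns(W), 0.5)
  expect_equal(igraph::as_adjacency_matrix(got, sparse = FALSE),
               igraph::as_adjacency_matrix(toy$truth, sparse = FALSE),
               ignore_attr = TRUE)
  # extreme thresholds: empty and complete graphs
  expect_equal(igraph::ecount(reconstruct(toy$wns, 1.0)), 0)
  expect_equal(igraph::ecount(reconstruct(toy$wns, -0.1)), 15)
})
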