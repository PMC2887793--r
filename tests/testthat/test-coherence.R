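test_that("global order parameter: locked population, balanced cancellation, incoherent baseline", {
  # identical phases at all times
  expect_equal(global_order_parameter(fake_record(matrix(1.2, 5, 8))), 1)
  # phases at the 4th roots of unity cancel exactly
  roots <- matrix(rep(c(0, pi / 2, pi, -pi / 2), each = 3), nrow = 3)
  expect_equal(global_order_parameter(fake_record(roots)), 0, tolerance = 1e-12)
  # i.i.d. uniform phases: E|mean phasor| ~ sqrt(pi)/(2 sqrt(N))
  set.seed(1)
  draws <- replicate(200, global_order_parameter(
    fake_record(matrix(runif(512, -pi, pi), 1))))
  expected <- sqrt(pi) / (2 * sqrt(512))
  expect_lt(abs(mean(draws) - expected), 3 * sd(draws) / sqrt(200))
  expect_error(global_order_parameter(fake_record(matrix(0, 0, 4))), "empty")
})

test_that("local order parameter: coherent neighborhoods, leaves, incoherent star", {
  star <- igraph::make_star(101, mode = "undirected", center = 1)
  # all neighbors of the hub share one phase -> r = 1 everywhere
  rec <- fake_record(matrix(0.5, 4, 101))
  expect_equal(local_order_parameter(rec, star), rep(1, 101))
  # leaves have k = 1: single unit phasor, r = 1 regardless of phase
  set.seed(2)
  rnd <- fake_record(matrix(runif(101 * 50, -pi, pi), 50))
  r <- local_order_parameter(rnd, star)
  expect_equal(unname(r[-1]), rep(1, 100))
  # the hub averages 100 random phasors: E|.| ~ sqrt(pi)/(2 sqrt(100))
  hubs <- replicate(60, local_order_parameter(
    fake_record(matrix(runif(101, -pi, pi), 1)), star)[1])
  expect_lt(abs(mean(hubs) - sqrt(pi) / 20), 3 * sd(hubs) / sqrt(60))
  # isolated node is an error
  iso <- igraph::make_empty_graph(3, directed = FALSE)
  expect_error(local_order_parameter(fake_record(matrix(0, 2, 3)), iso),
               "[Ii]solated")
})

test_that("effective coupling is K k r with hub/leaf ratio set by degree", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  r <- rep(0.5, 5)
  expect_equal(effective_coupling(0, star, r), rep(0, 5))
  expect_equal(unname(effective_coupling(0.1, star, rep(1, 5))[1]), 0.4)
  ec <- effective_coupling(0.2, star, r)
  expect_equal(unname(ec[1] / ec[2]), 4) # degree 4 hub vs degree 1 leaf
  expect_error(effective_coupling(1, star, c(2, r[-1])), "0, 1")
})

test_that("pairwise phase coherence matches closed forms for locked and drifting pairs", {
  t <- seq(0, 99.9, by = 0.1)
  # constant offset: locked pair, C = 1
  locked <- fake_record(cbind(0.3 + 0 * t, -1.1 + 0 * t))
  expect_equal(unclass(pairwise_phase_coherence(locked))[1, 2], 1,
               tolerance = 1e-12)
  # uniform relative drift: C equals the modulus of the mean rotating phasor
  dw <- 0.5
  drifting <- fake_record(cbind(dw * t, 0 * t))
  got <- unclass(pairwise_phase_coherence(drifting))[1, 2]
  expect_equal(got, Mod(mean(exp(1i * dw * t))), tolerance = 1e-12)
  expect_lt(got, 0.05) # dw * T >> 1 decoheres the pair
})

test_that("WNS weights are symmetric, unit-diagonal, in [0, 1], and wrap/shift invariant", {
  x <- tiny_ba_record()
  W <- pairwise_phase_coherence(x$rec)
  expect_equal(unclass(W), t(unclass(W)))
  expect_equal(diag(W), rep(1, x$rec$n_nodes))
  expect_true(all(W >= 0 & W <= 1))
  # a global phase shift leaves every pair weight unchanged
  shifted <- x$rec
  shifted$phases <- netsync:::wrap_phase(shifted$phases + 2.1)
  expect_equal(unclass(pairwise_phase_coherence(shifted)), unclass(W),
               tolerance = 1e-10)
})

test_that("averaging WNSs is element-wise and reduces run-to-run variance", {
  x <- tiny_ba_record(n = 16)
  W <- pairwise_phase_coherence(x$rec)
  expect_equal(unclass(average_wns(list(W, W, W))), unclass(W),
               ignore_attr = TRUE)
  A <- fake_wns(matrix(0, 4, 4)); B <- fake_wns(matrix(1, 4, 4))
  avg <- average_wns(list(A, B))
  expect_equal(netsync:::upper_weights(avg), rep(0.5, 6))
  expect_error(average_wns(list(A, fake_wns(matrix(1, 5, 5)))), "size")
  # ensemble averaging shrinks the spread of disconnected-pair weights
  g <- generate_ba(24, 2, seed = 31)
  wns_of <- function(seed) pairwise_phase_coherence(
    simulate_phases(g, K = 0.05, t_transient = 10, t_measure = 30,
                    seed = seed))
  singles <- lapply(1:10, wns_of)
  v_single <- mean(sapply(singles, function(w) var(netsync:::upper_weights(w))))
  v_avg <- var(netsync:::upper_weights(average_wns(singles)))
  expect_lt(v_avg, v_single)
})

test_that("skeleton equals the exhaustively enumerated maximum spanning tree", {
  set.seed(3)
  for (i in 1:5) {
    W <- matrix(runif(25), 5, 5)
    wns <- fake_wns(W)
    sk <- skeleton(wns)
    expect_identical(nrow(sk$edges), 4L)
    expect_equal(sk$total_weight, max_tree_weight_oracle(unclass(wns)),
                 tolerance = 1e-12)
  }
  # equal weights: any spanning tree, total weight forced to (n-1) w
  eq <- fake_wns(matrix(0.37, 6, 6))
  expect_equal(skeleton(eq)$total_weight, 5 * 0.37, tolerance = 1e-12)
  # n = 2: the single edge
  two <- fake_wns(matrix(c(1, 0.8, 0.8, 1), 2, 2))
  expect_identical(skeleton(two)$edges$node_a, 1)
  expect_equal(skeleton(two)$edges$weight, 0.8)
})

test_that("skeleton beats random spanning trees on simulated coherence", {
  x <- tiny_ba_record(n = 20)
  W <- pairwise_phase_coherence(x$rec)
  sk <- skeleton(W)
  set.seed(4)
  for (i in 1:20) {
    e <- prufer_to_tree(sample.int(20, 18, replace = TRUE), 20)
    expect_gte(sk$total_weight, sum(unclass(W)[e]))
  }
})

test_that("CLRP: identity, an adjacent rank swap, and the random-ordering level", {
  set.seed(5)
  W <- fake_wns(matrix(runif(25), 5, 5)) # L = 10 distinct weights
  expect_equal(clrp(W, W), 1)
  # swap the weights of the links ranked r and r+1: clrp = 1 - 2/L^2 = 0.98
  w <- netsync:::upper_weights(W)
  o <- order(-w)
  w2 <- w; w2[o[3]] <- w[o[4]]; w2[o[4]] <- w[o[3]]
  W2 <- unclass(W); W2[upper.tri(W2)] <- w2
  W2[lower.tri(W2)] <- t(W2)[lower.tri(W2)]
  expect_equal(clrp(W, fake_wns(W2)), 0.98)
  # independent random orderings: E[CLRP] = 1 - (L^2 - 1)/(3 L^2) ~ 2/3
  vals <- replicate(100, clrp(fake_wns(matrix(runif(900), 30, 30)),
                              fake_wns(matrix(runif(900), 30, 30))))
  expect_lt(abs(mean(vals) - 2 / 3), 0.02)
  expect_error(clrp(W, fake_wns(matrix(1, 6, 6))), "size")
})

test_that("connection-split and degree-product summaries are consistent with the WNS", {
  x <- tiny_ba_record(n = 24)
  W <- pairwise_phase_coherence(x$rec)
  bc <- coherence_by_connection(W, x$net)
  expect_equal(sum(bc$n_pairs), 24 * 23 / 2)
  expect_equal(bc$n_pairs[bc$pair_type == "connected"],
               as.integer(igraph::ecount(x$net)))
  ut <- upper.tri(W)
  expect_equal(sum(bc$mean * bc$n_pairs) / sum(bc$n_pairs),
               mean(unclass(W)[ut]))
  dp <- coherence_by_degree_product(W, x$net)
  expect_equal(sum(dp$n_pairs), 24 * 23 / 2)
  expect_true(all(dp$mean_coherence >= 0 & dp$mean_coherence <= 1))
})

test_that("WNS TSV round trip and top-L edge-list export", {
  x <- tiny_ba_record(n = 12)
  W <- pairwise_phase_coherence(x$rec)
  path <- withr::local_tempfile()
  write_wns(W, path)
  expect_equal(unclass(read_wns(path)), unclass(W), tolerance = 1e-14,
               ignore_attr = TRUE)
  path2 <- withr::local_tempfile()
  write_wns_edgelist(W, path2, top_l = 5)
  lines <- read.table(path2, sep = "\t")
  expect_identical(nrow(lines), 5L)
  expect_equal(sort(lines$V3, decreasing = TRUE),
               sort(netsync:::upper_weights(W), decreasing = TRUE)[1:5],
               tolerance = 1e-14)
})
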