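test_that("initial configurations follow the stated uniform laws", {
  ic <- draw_initial_configuration(512, seed = 1)
  expect_identical(nrow(ic), 512L)
  expect_true(all(ic$theta0 >= -pi & ic$theta0 <= pi))
  expect_true(all(ic$omega >= -0.1 & ic$omega <= 0.1))
  expect_lt(abs(mean(ic$omega)), 0.01)

  one <- draw_initial_configuration(1, seed = 2)
  expect_identical(nrow(one), 1L)

  big <- draw_initial_configuration(1e4, seed = 3)
  expect_lt(abs(var(big$omega) - 0.2^2 / 12) / (0.2^2 / 12), 0.05)
  expect_identical(draw_initial_configuration(16, seed = 9),
                   draw_initial_configuration(16, seed = 9))
})

test_that("drift matches hand values and the per-edge double-loop oracle", {
  pair <- igraph::make_graph(c(1, 2), directed = FALSE)
  expect_equal(kuramoto_drift(c(0, pi / 2), c(0, 0), 1, pair), c(1, -1))
  # K = 0 leaves only the intrinsic frequencies
  g <- generate_ba(20, 2, seed = 5)
  th <- runif(20, -pi, pi); om <- runif(20, -0.1, 0.1)
  expect_equal(kuramoto_drift(th, om, 0, g), om)
  for (K in c(0.05, 1)) {
    expect_equal(kuramoto_drift(th, om, K, g), drift_oracle(th, om, K, g),
                 tolerance = 1e-12)
  }
  expect_error(kuramoto_drift(th[-1], om, 1, g), "length")
})

test_that("noise-free integration of an uncoupled node is exact (state-independent drift)", {
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  init <- tibble::tibble(node = 1L, theta0 = 0.3, omega = 0.1)
  rec <- simulate_phases(g1, K = 0, D = 0, dt = 0.01, t_transient = 0,
                         t_measure = 1, stride = 1L, init = init,
                         keep_unwrapped = TRUE)
  expect_equal(nrow(rec$phases), 100L)
  expect_equal(rec$unwrapped[100, 1], 0.3 + 0.1, tolerance = 1e-12)
})

test_that("two coupled identical oscillators relax monotonically to in-phase", {
  pair <- igraph::make_graph(c(1, 2), directed = FALSE)
  init <- tibble::tibble(node = 1:2, theta0 = c(0.3, -0.3), omega = c(0, 0))
  rec <- simulate_phases(pair, K = 1, D = 0, t_transient = 0, t_measure = 5,
                         stride = 1L, init = init, keep_unwrapped = TRUE)
  gap <- abs(rec$unwrapped[, 1] - rec$unwrapped[, 2])
  expect_true(all(diff(gap) < 1e-12))
  expect_lt(gap[length(gap)], 1e-3)
})

test_that("deterministic Heun converges at second order in dt", {
  g <- generate_ba(10, 2, seed = 8)
  init <- draw_initial_configuration(10, seed = 9)
  final <- function(dt) {
    rec <- simulate_phases(g, K = 1, D = 0, dt = dt, t_transient = 0,
                           t_measure = 1, stride = round(1 / dt),
                           init = init, keep_unwrapped = TRUE)
    rec$unwrapped[nrow(rec$unwrapped), ]
  }
  ref <- final(0.001)
  e1 <- sqrt(mean((final(0.02) - ref)^2))
  e2 <- sqrt(mean((final(0.01) - ref)^2))
  expect_gt(e1 / e2, 3) # ~4 for a second-order scheme
  expect_lt(e1 / e2, 5.5)
})

test_that("a global phase shift propagates unchanged through noise-free dynamics", {
  g <- generate_ba(12, 2, seed = 10)
  init <- draw_initial_configuration(12, seed = 11)
  shifted <- dplyr::mutate(init, theta0 = theta0 + 0.7)
  r1 <- simulate_phases(g, K = 0.5, D = 0, t_transient = 0, t_measure = 5,
                        init = init, keep_unwrapped = TRUE)
  r2 <- simulate_phases(g, K = 0.5, D = 0, t_transient = 0, t_measure = 5,
                        init = shifted, keep_unwrapped = TRUE)
  expect_equal(r2$unwrapped, r1$unwrapped + 0.7, tolerance = 1e-8)
})

test_that("strong coupling without noise reaches near-perfect global order", {
  g <- generate_ba(24, 2, seed = 12)
  init <- dplyr::mutate(draw_initial_configuration(24, seed = 13), omega = 0)
  rec <- simulate_phases(g, K = 1, D = 0, t_transient = 50, t_measure = 10,
                         init = init)
  expect_gt(global_order_parameter(rec), 0.999)
})

test_that("uncoupled noisy phases diffuse with variance 2 D t", {
  n <- 500; D <- 0.01; t_end <- 50
  g <- igraph::make_empty_graph(n, directed = FALSE)
  init <- tibble::tibble(node = seq_len(n), theta0 = 0, omega = 0)
  rec <- simulate_phases(g, K = 0, D = D, t_transient = 0, t_measure = t_end,
                         stride = 50L, init = init, seed = 14,
                         keep_unwrapped = TRUE)
  for (s in c(10, nrow(rec$unwrapped))) {
    t_s <- rec$times[s]
    v <- var(rec$unwrapped[s, ])
    expect_lt(abs(v - 2 * D * t_s) / (2 * D * t_s), 0.25)
  }
})

test_that("identical (net, config, init, seed) reproduces the record bit-exactly", {
  g <- generate_ba(16, 2, seed = 15)
  r1 <- simulate_phases(g, K = 0.1, t_transient = 1, t_measure = 5, seed = 16)
  r2 <- simulate_phases(g, K = 0.1, t_transient = 1, t_measure = 5, seed = 16)
  expect_identical(r1$phases, r2$phases)
  r3 <- simulate_phases(g, K = 0.1, t_transient = 1, t_measure = 5, seed = 17)
  expect_false(identical(r1$phases, r3$phases))
})

test_that("records carry uniformly spaced times, wrapped finite phases", {
  x <- tiny_ba_record()
  rec <- x$rec
  expect_true(all(abs(diff(rec$times) - rec$dt_eff) < 1e-9))
  expect_true(all(is.finite(rec$phases)))
  expect_true(all(rec$phases > -pi & rec$phases <= pi))
})

test_that("phase-record TSV round trip preserves data and metadata", {
  x <- tiny_ba_record(n = 12, t_measure = 3)
  path <- withr::local_tempfile()
  write_phase_record(x$rec, path)
  back <- read_phase_record(path)
  expect_equal(back$phases, x$rec$phases, tolerance = 1e-14)
  expect_equal(back$times, x$rec$times)
  expect_identical(back$n_nodes, x$rec$n_nodes)
  expect_equal(back$K, x$rec$K)
})
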