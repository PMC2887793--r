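# Noisy Kuramoto dynamics on a substrate network:
#   dtheta_i/dt = omega_i + K * sum_j A_ij sin(theta_j - theta_i) + xi_i(t),
# with Gaussian white noise <xi_i(t) xi_j(t')> = 2 D delta_ij delta(t - t'),
# integrated by the stochastic Heun (improved Euler) scheme in src/heun.cpp.

#' Draw a random initial configuration
#'
#' Initial phases uniform on [-pi, pi] and intrinsic frequencies uniform on
#' [-0.1, 0.1] radians per time unit, independently per node.
#'
#' @param n_nodes number of oscillators
#' @param seed integer seed; `NULL` uses the current RNG stream
#' @return a tibble with columns `node`, `theta0`, `omega`
#' @export
draw_initial_configuration <- function(n_nodes, seed = NULL) {
  stopifnot(n_nodes >= 1)
  with_seed(seed, tibble::tibble(
    node = seq_len(n_nodes),
    theta0 = runif(n_nodes, -pi, pi),
    omega = runif(n_nodes, -0.1, 0.1)
  ))
}

#' Deterministic drift of the Kuramoto system
#'
#' Returns omega_i + K * sum over the neighbors j of i of sin(theta_j -
#' theta_i), the noise-free right-hand side of the equations of motion.
#' Vectorized through the adjacency matrix; the compiled integrator uses an
#' equivalent edge-wise accumulation.
#'
#' @param theta phase vector (radians), length = node count of `net`
#' @param omega intrinsic frequency vector, same length
#' @param K coupling strength (>= 0)
#' @param net the substrate `igraph` graph
#' @return the rate-of-change vector dtheta/dt
#' @export
kuramoto_drift <- function(theta, omega, K, net) {
  n <- igraph::vcount(net)
  if (length(theta) != n || length(omega) != n)
    stop("theta/omega length must equal the node count of `net`")
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  # sum_j A_ij sin(theta_j - theta_i) = cos(theta_i) [A sin(theta)]_i
  #                                   - sin(theta_i) [A cos(theta)]_i
  omega + K * (cos(theta) * as.vector(A %*% sin(theta)) -
                 sin(theta) * as.vector(A %*% cos(theta)))
}

# Wrap to (-pi, pi].
wrap_phase <- function(x) pi - ((pi - x) %% (2 * pi))

#' Simulate noisy Kuramoto dynamics and record sampled phases
#'
#' Integrates the system with the stochastic Heun predictor-corrector: one
#' additive Gaussian increment of standard deviation sqrt(2 D dt) per node per
#' step, shared between the predictor and corrector stages (so the scheme
#' reduces to deterministic second-order Heun at D = 0).  The first
#' `t_transient` time units are discarded; every `stride`-th step of the
#' following `t_measure` time units is recorded.
#'
#' @param net substrate `igraph` graph
#' @param K coupling strength (>= 0)
#' @param D noise intensity (>= 0)
#' @param dt integration step (time units)
#' @param t_transient warm-up duration to discard (time units)
#' @param t_measure measurement duration (time units)
#' @param stride integer steps between recorded samples
#' @param init initial configuration as returned by
#'   [draw_initial_configuration()]; `NULL` draws one from the run's stream
#' @param seed integer seed for noise (and `init`, when drawn here)
#' @param keep_unwrapped also retain the unwrapped phases (for diffusion
#'   diagnostics); doubles the memory footprint
#' @return a `phase_record`: list with `times`, `phases` (samples x nodes,
#'   wrapped to (-pi, pi]), the `init` tibble, and the run parameters
#' @export
#' @examples
#' g <- generate_ba(32, 2, seed = 1)
#' rec <- simulate_phases(g, K = 0.05, t_transient = 5, t_measure = 10, seed = 2)
#' global_order_parameter(rec)
simulate_phases <- function(net, K, D = 0.01, dt = 0.01,
                            t_transient = 500, t_measure = 1000,
                            stride = 10L, init = NULL, seed = NULL,
                            keep_unwrapped = FALSE) {
  stopifnot(K >= 0, D >= 0, dt > 0, t_measure > 0, t_transient >= 0,
            stride >= 1)
  n <- as.integer(igraph::vcount(net))
  el <- igraph::as_edgelist(net, names = FALSE) - 1L
  n_tr <- as.integer(round(t_transient / dt))
  n_me <- as.integer(round(t_measure / dt))
  if (n_me %/% stride < 1) stop("t_measure too short to record a sample")
  rec <- with_seed(seed, {
    if (is.null(init)) init <- draw_initial_configuration(n)
    if (nrow(init) != n) stop("init has ", nrow(init), " rows for ", n, " nodes")
    un <- .heun_kuramoto(as.integer(el[, 1]), as.integer(el[, 2]), n,
                         init$theta0, init$omega, K, D, dt,
                         n_tr, n_me, as.integer(stride))
    list(init = init, unwrapped = un)
  })
  s <- nrow(rec$unwrapped)
  structure(list(
    times = t_transient + dt * stride * seq_len(s),
    phases = wrap_phase(rec$unwrapped),
    unwrapped = if (keep_unwrapped) rec$unwrapped,
    init = rec$init,
    n_nodes = n, K = K, D = D, dt = dt, stride = as.integer(stride),
    dt_eff = dt * stride, t_transient = t_transient, t_measure = t_measure,
    seed = seed
  ), class = "phase_record")
}

#' @export
print.phase_record <- function(x, ...) {
  cat(sprintf(
    "<phase_record> %d nodes, %d samples every %g time units (t in [%g, %g])\n",
    x$n_nodes, length(x$times), x$dt_eff, x$times[1],
    x$times[length(x$times)]))
  cat(sprintf("  K = %g, D = %g, dt = %g, seed = %s\n", x$K, x$D, x$dt,
              if (is.null(x$seed)) "<stream>" else format(x$seed)))
  invisible(x)
}

#' Write a phase record as a headered TSV matrix
#'
#' Dense numeric matrix (rows = time samples, columns = nodes) preceded by
#' `#`-prefixed header lines carrying n, dt_eff, the first sample time and the
#' run parameters.
#'
#' @param rec a `phase_record`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_phase_record <- function(rec, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf(
    "# netsync phase_record\n# n=%d dt_eff=%.10g t0=%.10g K=%.10g D=%.10g dt=%.10g stride=%d",
    rec$n_nodes, rec$dt_eff, rec$times[1], rec$K, rec$D, rec$dt, rec$stride)
  writeLines(hdr, con = con, sep = "\n")
  write.table(format(rec$phases, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a phase record written by [write_phase_record()]
#'
#' @param path input file path
#' @return a `phase_record`
#' @export
read_phase_record <- function(path) {
  lines <- readLines(path, n = 2)
  if (!startsWith(lines[1], "# netsync phase_record"))
    stop("not a netsync phase_record file: ", path)
  kv <- strsplit(sub("^# ", "", lines[2]), " ")[[1]]
  kv <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  ph <- as.matrix(read.table(path, header = FALSE, comment.char = "#",
                             sep = "\t"))
  dimnames(ph) <- NULL
  s <- nrow(ph)
  structure(list(
    times = kv[["t0"]] + kv[["dt_eff"]] * (seq_len(s) - 1),
    phases = ph, unwrapped = NULL, init = NULL,
    n_nodes = as.integer(kv[["n"]]), K = kv[["K"]], D = kv[["D"]],
    dt = kv[["dt"]], stride = as.integer(kv[["stride"]]),
    dt_eff = kv[["dt_eff"]], t_transient = NA_real_, t_measure = NA_real_,
    seed = NULL
  ), class = "phase_record")
}
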