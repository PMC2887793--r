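# Finite-size scaling analysis of the synchronization transition.  The global
# order parameter is assumed to obey R(K, N) = N^(-beta/nu) F((K - K_c)
# N^(1/nu)): rescaled curves R N^(beta/nu) for different sizes N cross at K_c
# for the right exponent ratio, and the derivative dR/dK at K_c scales as
# N^((1-beta)/nu).

#' Scan the global order parameter over sizes and couplings
#'
#' For each (N, K) cell, generates a fresh substrate and initial configuration
#' per replicate (quenched-disorder averaging over both), simulates, and
#' records the mean and standard error of the global order parameter.
#'
#' @param model generator: a function `(n_nodes, seed)` returning an `igraph`
#'   graph; defaults to BA with m = 2
#' @param sizes network sizes (>= 3 distinct values for crossing analysis)
#' @param K_grid strictly increasing coupling values
#' @param replicates independent (substrate, configuration) draws per size;
#'   each replicate keeps its substrate and initial configuration fixed
#'   across the whole K sweep (only the noise stream varies with K), so a
#'   replicate traces a smooth curve in K and crossings between sizes are not
#'   blurred by quenched-disorder resampling
#' @param D,dt,t_transient,t_measure,stride passed to [simulate_phases()]
#' @param seed master seed; per-run seeds derive from (size, replicate, K)
#' @return a `scaling_curves` tibble: `N`, `K`, `R_mean`, `R_se`, `replicates`
#' @export
scan_order_parameter <- function(model = function(n, seed) generate_ba(n, 2, seed),
                                 sizes = c(64, 128, 256),
                                 K_grid = seq(0.005, 0.05, length.out = 10),
                                 replicates = 5,
                                 D = 0.01, dt = 0.01,
                                 t_transient = 250, t_measure = 500,
                                 stride = 10L, seed = 1) {
  stopifnot(replicates >= 1, all(diff(K_grid) > 0))
  grid <- tidyr::expand_grid(N = sizes, K = K_grid,
                             rep = seq_len(replicates))
  grid$R <- purrr::pmap_dbl(grid, function(N, K, rep) {
    cell_seed <- derive_seed(seed, which(sizes == N), rep)
    net <- model(N, derive_seed(cell_seed, 1))
    init <- draw_initial_configuration(N, derive_seed(cell_seed, 2))
    rec <- tryCatch(
      simulate_phases(net, K = K, D = D, dt = dt,
                      t_transient = t_transient, t_measure = t_measure,
                      stride = stride, init = init,
                      seed = derive_seed(cell_seed, 3, which(K_grid == K))),
      error = function(e) stop("simulation failed at (N = ", N, ", K = ", K,
                               ", replicate = ", rep, "): ",
                               conditionMessage(e), call. = FALSE))
    global_order_parameter(rec)
  })
  out <- grid |>
    dplyr::group_by(.data$N, .data$K) |>
    dplyr::summarise(R_mean = mean(.data$R),
                     R_se = if (dplyr::n() > 1) sd(.data$R) / sqrt(dplyr::n())
                            else NA_real_,
                     replicates = dplyr::n(), .groups = "drop")
  class(out) <- c("scaling_curves", class(out))
  out
}

# Piecewise-linear crossing abscissae of two curves sampled on a common K
# grid.  Returns numeric(0) when the curves never cross; when the two curves
# coincide to machine precision the pair is flagged degenerate.
pair_crossings <- function(K, y1, y2, separated = rep(TRUE, length(K))) {
  d <- y1 - y2
  if (max(abs(d)) < 1e-12) return(structure(numeric(0), degenerate = TRUE))
  out <- K[d == 0 & separated]
  s <- d[-length(d)] * d[-1]
  i <- which(s < 0)
  # keep a sign change only if the curves were genuinely separated at some
  # coupling below it (filters noise crossings inside a coincidence region)
  i <- i[vapply(i, function(j) any(separated[seq_len(j)]), logical(1))]
  if (length(i))
    out <- c(out, K[i] - d[i] * (K[i + 1] - K[i]) / (d[i + 1] - d[i]))
  structure(sort(out), degenerate = FALSE)
}

#' Locate the critical coupling by the rescaled-curve crossing method
#'
#' For each candidate exponent ratio beta/nu, rescales every size's curve to
#' R N^(beta/nu), collects all pairwise crossing abscissae (piecewise-linear
#' interpolation in K), and scores the candidate by the standard deviation of
#' those abscissae.  The best candidate's mean crossing abscissa is K_c.
#'
#' When the curves carry standard errors, a crossing is only counted if the
#' two rescaled curves are statistically separated (by more than
#' `z_sep` pooled standard errors) somewhere below it.  This excludes the
#' spurious crossing clusters produced by the trivial incoherent-phase
#' collapse (R ~ N^(-1/2) below the transition makes rescaled curves
#' coincide over the whole weak-coupling range near ratio 1/2, where noise
#' alone generates tightly clustered sign changes).
#'
#' @param curves a `scaling_curves` tibble (>= 3 sizes)
#' @param ratio_grid candidate beta/nu values
#' @param z_sep significance multiple for the separation filter (ignored
#'   when the curves carry no standard errors)
#' @return a list: `K_c`, `beta_over_nu`, `crossing_dispersion`,
#'   `n_crossings`, `degenerate` (TRUE when the best candidate's curves are
#'   N-independent and the crossing point is undefined)
#' @export
find_crossing <- function(curves, ratio_grid = seq(0, 1, by = 0.01),
                          z_sep = 2) {
  sizes <- sort(unique(curves$N))
  if (length(sizes) < 3) stop("need at least 3 distinct sizes")
  if (!length(ratio_grid)) stop("empty ratio_grid")
  K <- sort(unique(curves$K))
  Rm <- sapply(sizes, function(n) {
    ci <- curves[curves$N == n, ]
    ci$R_mean[match(K, ci$K)]
  })
  has_se <- "R_se" %in% names(curves) && !anyNA(curves$R_se)
  Sm <- if (has_se) sapply(sizes, function(n) {
    ci <- curves[curves$N == n, ]
    ci$R_se[match(K, ci$K)]
  }) else NULL
  pairs <- utils::combn(length(sizes), 2)
  best <- NULL
  for (b in ratio_grid) {
    Y <- sweep(Rm, 2, sizes^b, `*`)
    S <- if (has_se) sweep(Sm, 2, sizes^b, `*`) else NULL
    cross <- list(); degen <- logical(0)
    for (p in seq_len(ncol(pairs))) {
      sep <- if (has_se) {
        abs(Y[, pairs[1, p]] - Y[, pairs[2, p]]) >
          z_sep * sqrt(S[, pairs[1, p]]^2 + S[, pairs[2, p]]^2)
      } else rep(TRUE, length(K))
      cr <- pair_crossings(K, Y[, pairs[1, p]], Y[, pairs[2, p]], sep)
      degen <- c(degen, attr(cr, "degenerate"))
      if (length(cr)) cross[[length(cross) + 1]] <- cr
    }
    if (all(degen)) {
      cand <- list(K_c = NA_real_, beta_over_nu = b, crossing_dispersion = 0,
                   n_crossings = 0L, degenerate = TRUE)
    } else {
      xs <- unlist(cross)
      n_pairs_used <- length(cross)
      if (n_pairs_used < 2 || length(xs) < 2) next
      cand <- list(K_c = mean(xs), beta_over_nu = b,
                   crossing_dispersion = sd(xs),
                   n_crossings = length(xs), degenerate = FALSE)
    }
    if (is.null(best) || cand$crossing_dispersion < best$crossing_dispersion)
      best <- cand
  }
  if (is.null(best))
    stop("no candidate ratio produced crossings for at least two size pairs")
  best
}

#' Derivative-scaling exponent (1 - beta)/nu at the critical coupling
#'
#' Estimates dR/dK at K_c for every size by a centered difference on the
#' piecewise-linearly interpolated curve (bandwidth = one K-grid step) and
#' fits log(dR/dK) against log(N) by least squares; the slope is
#' (1 - beta)/nu.
#'
#' @param curves a `scaling_curves` tibble
#' @param K_c critical coupling, strictly inside the K grid
#' @return the slope, with attributes `derivatives` (per-size tibble) and
#'   `unreliable` (TRUE for a two-size fit)
#' @export
derivative_exponent <- function(curves, K_c) {
  K <- sort(unique(curves$K))
  if (K_c <= min(K) || K_c >= max(K))
    stop("K_c must lie strictly inside the K grid")
  h <- min(median(diff(K)), K_c - min(K), max(K) - K_c)
  sizes <- sort(unique(curves$N))
  dRdK <- vapply(sizes, function(n) {
    ci <- curves[curves$N == n, ]
    f <- approx(ci$K, ci$R_mean, xout = c(K_c - h, K_c + h))$y
    (f[2] - f[1]) / (2 * h)
  }, numeric(1))
  if (any(dRdK <= 0))
    stop("non-positive dR/dK at K_c for N in {",
         paste(sizes[dRdK <= 0], collapse = ", "),
         "}: transition not captured by the scan")
  fit <- lm(log(dRdK) ~ log(sizes))
  slope <- unname(coef(fit)[2])
  attr(slope, "derivatives") <- tibble::tibble(N = sizes, dRdK = dRdK)
  attr(slope, "unreliable") <- length(sizes) == 2
  slope
}

#' Solve the critical exponents from the two measured ratios
#'
#' Given beta/nu and (1 - beta)/nu, nu = 1 / (beta/nu + (1 - beta)/nu) and
#' beta = nu * (beta/nu).
#'
#' @param beta_over_nu measured crossing ratio
#' @param one_minus_beta_over_nu measured derivative-scaling ratio
#' @return named numeric vector `c(beta = , nu = )`
#' @export
solve_exponents <- function(beta_over_nu, one_minus_beta_over_nu) {
  s <- beta_over_nu + one_minus_beta_over_nu
  if (!is.finite(s) || s <= 0) stop("degenerate exponent ratios (sum <= 0)")
  nu <- 1 / s
  c(beta = nu * beta_over_nu, nu = nu)
}

#' Full finite-size scaling fit
#'
#' Runs the crossing analysis, the derivative-scaling fit at the located K_c,
#' and solves for (beta, nu).
#'
#' @inheritParams find_crossing
#' @return an `fss_fit` object; see [tidy()] and [glance()] methods
#' @export
#' @examples
#' K <- seq(0.005, 0.05, length.out = 12)
#' curves <- tidyr::expand_grid(N = c(64, 128, 256), K = K) |>
#'   dplyr::mutate(R_mean = N^-0.25 * (0.5 + 0.4 * tanh((K - 0.02) * N^0.5)),
#'                 R_se = NA_real_, replicates = 1L)
#' fit <- fss_fit(curves)
#' glance(fit)
fss_fit <- function(curves, ratio_grid = seq(0, 1, by = 0.01)) {
  cr <- find_crossing(curves, ratio_grid)
  if (cr$degenerate)
    stop("size-independent curves: scaling collapse is degenerate at ",
         "beta/nu = ", cr$beta_over_nu)
  de <- derivative_exponent(curves, cr$K_c)
  ex <- solve_exponents(cr$beta_over_nu, as.numeric(de))
  structure(list(
    K_c = cr$K_c, beta_over_nu = cr$beta_over_nu,
    one_minus_beta_over_nu = as.numeric(de),
    beta = unname(ex["beta"]), nu = unname(ex["nu"]),
    crossing_dispersion = cr$crossing_dispersion,
    n_crossings = cr$n_crossings,
    derivatives = attr(de, "derivatives"),
    curves = curves
  ), class = "fss_fit")
}

#' @export
print.fss_fit <- function(x, ...) {
  cat(sprintf(
    "<fss_fit> K_c = %.4f (crossing dispersion %.2g over %d crossings)\n",
    x$K_c, x$crossing_dispersion, x$n_crossings))
  cat(sprintf("  beta/nu = %.3f, (1-beta)/nu = %.3f  =>  beta = %.3f, nu = %.3f\n",
              x$beta_over_nu, x$one_minus_beta_over_nu, x$beta, x$nu))
  invisible(x)
}

#' Tidy a finite-size scaling fit
#' @param x an `fss_fit`
#' @param ... unused
#' @return a tibble with one row per estimated quantity
#' @exportS3Method generics::tidy
tidy.fss_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K_c", "beta_over_nu", "one_minus_beta_over_nu", "beta", "nu"),
    estimate = c(x$K_c, x$beta_over_nu, x$one_minus_beta_over_nu,
                 x$beta, x$nu))
}

#' One-row summary of a finite-size scaling fit
#' @param x an `fss_fit`
#' @param ... unused
#' @return a one-row tibble
#' @exportS3Method generics::glance
glance.fss_fit <- function(x, ...) {
  tibble::tibble(K_c = x$K_c, beta = x$beta, nu = x$nu,
                 crossing_dispersion = x$crossing_dispersion,
                 n_crossings = x$n_crossings,
                 n_sizes = length(unique(x$curves$N)))
}

#' Write scaling curves as a tidy TSV table
#' @param curves a `scaling_curves` tibble
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_scaling_curves <- function(curves, path) {
  write.table(as.data.frame(curves), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read scaling curves written by [write_scaling_curves()]
#' @param path input file path
#' @return a `scaling_curves` tibble
#' @export
read_scaling_curves <- function(path) {
  out <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t"))
  class(out) <- c("scaling_curves", class(out))
  out
}
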