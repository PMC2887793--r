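# Substrate-network generators: BA preferential attachment, random regular,
# and the power-law-with-exponential-cutoff family P(k) ~ k^-gamma e^(-k/kappa)
# at fixed mean degree.  All generators return simple, connected igraph objects
# and are bit-reproducible under an explicit integer seed.

#' Generate a Barabasi-Albert scale-free network
#'
#' Growth with preferential attachment: the seed graph is the complete graph
#' on `m` nodes; every subsequent node attaches to `m` distinct existing nodes
#' chosen with probability proportional to their current degree.  The
#' resulting degree distribution approaches P(k) ~ k^-3 with mean degree close
#' to 2m.
#'
#' @param n_nodes number of nodes (> m)
#' @param m edges added per new node (>= 1)
#' @param seed integer seed; `NULL` uses (and advances) the current RNG stream
#' @return an undirected, simple, connected `igraph` graph
#' @export
#' @examples
#' g <- generate_ba(128, m = 2, seed = 1)
#' mean(igraph::degree(g))
generate_ba <- function(n_nodes, m = 2, seed = NULL) {
  if (m < 1) stop("m must be >= 1")
  if (n_nodes <= m) stop("n_nodes must exceed m")
  with_seed(seed, {
    seed_edges <- if (m >= 2) t(utils::combn(m, 2)) else matrix(0L, 0, 2)
    edges <- matrix(0L, nrow = nrow(seed_edges) + (n_nodes - m) * m, ncol = 2)
    if (nrow(seed_edges)) edges[seq_len(nrow(seed_edges)), ] <- seed_edges
    n_e <- nrow(seed_edges)
    # pool holds one entry per edge endpoint: sampling uniformly from it is
    # sampling nodes proportionally to degree
    pool <- integer(2 * nrow(edges))
    pool[seq_len(2 * n_e)] <- as.integer(t(seed_edges))
    n_p <- 2 * n_e
    if (m == 1 && n_p == 0) { # degree-0 seed node: first attachment is forced
      pool[1] <- 1L
      n_p <- 1L
    }
    for (v in (m + 1):n_nodes) {
      chosen <- integer(0)
      while (length(chosen) < m) {
        cand <- pool[sample.int(n_p, 1L)]
        if (!(cand %in% chosen)) chosen <- c(chosen, cand)
      }
      for (u in chosen) {
        n_e <- n_e + 1L
        edges[n_e, ] <- c(u, v)
        pool[n_p + 1L] <- u
        pool[n_p + 2L] <- as.integer(v)
        n_p <- n_p + 2L
      }
    }
    g <- igraph::graph_from_edgelist(edges[seq_len(n_e), , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g)) # m = 1, n = 2 corner
    igraph::graph_attr(g, "model") <- "ba"
    g
  })
}

#' Generate a random k-regular network
#'
#' Uniform random simple graph in which every node has degree exactly `k`,
#' resampled until connected.  This is the sigma = 0 member of the
#' heterogeneity family.
#'
#' @inheritParams generate_ba
#' @param k degree of every node; `n_nodes * k` must be even and `k < n_nodes`
#' @param max_tries resampling attempts before giving up
#' @return an undirected, simple, connected `igraph` graph
#' @export
generate_regular <- function(n_nodes, k, seed = NULL, max_tries = 100) {
  if (k < 1 || k >= n_nodes) stop("need 1 <= k < n_nodes")
  if ((n_nodes * k) %% 2 != 0) stop("n_nodes * k must be even (handshake parity)")
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      g <- igraph::sample_k_regular(n_nodes, k)
      if (igraph::is_connected(g)) {
        igraph::graph_attr(g, "model") <- "regular"
        return(g)
      }
    }
    stop("no connected ", k, "-regular graph found in ", max_tries, " attempts")
  })
}

# Normalized pmf of P(k) ~ k^-gamma e^(-k/kappa) on k_min:k_max
# (log-sum-exp so extreme gamma values stay stable).
cutoff_pmf <- function(gamma, kappa, k_min, k_max) {
  k <- k_min:k_max
  lw <- -gamma * log(k) - k / kappa
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Moments of the cutoff degree distribution
#'
#' Mean and (population) standard deviation of P(k) ~ k^-gamma e^(-k/kappa)
#' restricted to `k_min:k_max`.
#'
#' @param gamma power-law exponent
#' @param kappa exponential cutoff scale (degree units)
#' @param k_min,k_max support bounds
#' @return a list with elements `mean` and `sd`
#' @export
cutoff_degree_moments <- function(gamma, kappa, k_min = 2, k_max = 45) {
  k <- k_min:k_max
  p <- cutoff_pmf(gamma, kappa, k_min, k_max)
  m <- sum(k * p)
  list(mean = m, sd = sqrt(sum((k - m)^2 * p)))
}

# Exponent that pins the distribution mean at mean_degree for a given kappa.
# The mean is strictly decreasing in gamma, so the root is unique.
solve_gamma_for_mean <- function(kappa, mean_degree, k_min, k_max) {
  lo <- -5000; hi <- 500
  f <- function(g) cutoff_degree_moments(g, kappa, k_min, k_max)$mean - mean_degree
  if (f(lo) < 0 || f(hi) > 0)
    stop("mean degree ", mean_degree, " unreachable on [", k_min, ", ", k_max,
         "] at kappa = ", kappa)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Default structural cutoff: above sqrt(<k> n) a simple-graph realization of a
# heavy-tailed sequence becomes unlikely.
default_k_max <- function(n_nodes, mean_degree) {
  max(3L, min(n_nodes - 1L, floor(sqrt(mean_degree * n_nodes))))
}

#' Generate a network from the power-law family with exponential cutoff
#'
#' Degrees are sampled from P(k) ~ k^-gamma e^(-k/kappa) on
#' k in [`k_min`, `k_max`]; the sequence is redrawn until its sum is even, it
#' is graphical, and its mean is within 2% of `mean_degree`; the graph is then
#' realized as a uniform simple connected graph with that exact degree
#' sequence (Viger-Latapy sampling).  By default `gamma` is solved internally
#' so the distribution mean equals `mean_degree` — holding the mean fixed
#' while `kappa` alone dials the degree heterogeneity sigma(kappa); see
#' [calibrate_kappa()].
#'
#' @inheritParams generate_ba
#' @param kappa exponential cutoff scale (degree units), > 0
#' @param gamma power-law exponent; `NULL` (default) solves it for the mean
#'   constraint.  A supplied value must already give the requested mean to
#'   within 2%.
#' @param mean_degree target mean degree
#' @param k_min,k_max degree support; `k_max = NULL` uses the structural
#'   cutoff floor(sqrt(mean_degree * n_nodes))
#' @param max_tries resampling attempts before giving up
#' @return an undirected, simple, connected `igraph` graph
#' @export
generate_cutoff <- function(n_nodes, kappa, gamma = NULL, mean_degree = 4,
                            k_min = 2, k_max = NULL, seed = NULL,
                            max_tries = 200) {
  if (kappa <= 0) stop("kappa must be positive")
  if (mean_degree <= 0) stop("mean_degree must be positive")
  if (is.null(k_max)) k_max <- default_k_max(n_nodes, mean_degree)
  if (mean_degree <= k_min || mean_degree >= k_max)
    stop("mean_degree must lie strictly inside [k_min, k_max]")
  if (is.null(gamma)) {
    gamma <- solve_gamma_for_mean(kappa, mean_degree, k_min, k_max)
  } else {
    got <- cutoff_degree_moments(gamma, kappa, k_min, k_max)$mean
    if (abs(got - mean_degree) / mean_degree > 0.02)
      stop("distribution mean ", signif(got, 4), " at (gamma, kappa) = (",
           signif(gamma, 4), ", ", signif(kappa, 4),
           ") misses mean_degree by more than 2%")
  }
  p <- cutoff_pmf(gamma, kappa, k_min, k_max)
  ks <- k_min:k_max
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      deg <- sample(ks, n_nodes, replace = TRUE, prob = p)
      while (sum(deg) %% 2 != 0) deg[sample.int(n_nodes, 1)] <-
          sample(ks, 1, prob = p)
      if (abs(mean(deg) - mean_degree) / mean_degree > 0.02) next
      if (!igraph::is_graphical(deg)) next
      g <- tryCatch(igraph::sample_degseq(deg, method = "vl"),
                    error = function(e) NULL)
      if (!is.null(g) && igraph::is_connected(g) && igraph::is_simple(g)) {
        igraph::graph_attr(g, "model") <- "cutoff"
        igraph::graph_attr(g, "kappa") <- kappa
        igraph::graph_attr(g, "gamma") <- gamma
        return(g)
      }
    }
    stop("no simple connected realization found in ", max_tries, " attempts")
  })
}

#' Standard deviation of a network's degree sequence
#'
#' Population standard deviation (denominator n) of the degree sequence —
#' the heterogeneity measure sigma: 0 for a regular graph, about 3 for a
#' BA graph with 512 nodes and mean degree 4.
#'
#' @param net an `igraph` graph
#' @return a single non-negative number
#' @export
#' @examples
#' degree_sigma(generate_regular(16, 4, seed = 1)) # exactly 0
degree_sigma <- function(net) {
  k <- igraph::degree(net)
  sqrt(mean((k - mean(k))^2))
}

#' Calibrate the cutoff scale kappa for a target degree heterogeneity
#'
#' Bisects kappa (with the exponent re-solved at every step to hold the mean
#' degree fixed) until the analytic standard deviation of the degree
#' distribution matches `target_sigma`.  sigma(kappa) is monotonically
#' increasing over the search range, spanning near-regular (sigma ~ 0.05) to
#' beyond scale-free (sigma > 4) at n = 512, mean degree 4.
#'
#' @param target_sigma desired degree-sequence standard deviation (>= 0)
#' @param n_nodes network size (sets the structural degree cutoff)
#' @param mean_degree fixed mean degree of the family
#' @param kappa_range search interval for kappa
#' @return the calibrated kappa, with the solved exponent attached as
#'   attribute `"gamma"`
#' @export
#' @examples
#' kap <- calibrate_kappa(3.0, n_nodes = 512)
#' degree_sigma(generate_cutoff(512, kap, seed = 1))
calibrate_kappa <- function(target_sigma, n_nodes = 512, mean_degree = 4,
                            kappa_range = c(0.01, 2000)) {
  if (target_sigma < 0) stop("target_sigma must be >= 0")
  k_min <- 2
  k_max <- default_k_max(n_nodes, mean_degree)
  sd_at <- function(kap) {
    g <- solve_gamma_for_mean(kap, mean_degree, k_min, k_max)
    cutoff_degree_moments(g, kap, k_min, k_max)$sd
  }
  lo <- kappa_range[1]; hi <- kappa_range[2]
  if (target_sigma <= sd_at(lo)) {
    kap <- lo # lower search bound: near-degenerate degrees
  } else if (target_sigma > sd_at(hi)) {
    stop("target_sigma = ", target_sigma, " exceeds the sigma achievable at ",
         "n = ", n_nodes, ", mean degree ", mean_degree)
  } else {
    kap <- exp(uniroot(function(lk) sd_at(exp(lk)) - target_sigma,
                       log(c(lo, hi)), tol = 1e-8)$root)
  }
  attr(kap, "gamma") <- solve_gamma_for_mean(kap, mean_degree, k_min, k_max)
  kap
}

#' Write a network as a plain edge list
#'
#' Two tab-separated 0-based integer node ids per line, one line per
#' undirected edge, smaller id first, no header, LF line endings.
#'
#' @param net an `igraph` graph
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net, names = FALSE) - 1L
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  con <- file(path, open = "wb") # wb: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), con = con, sep = "\n")
  invisible(path)
}

#' Read a network from a plain edge list
#'
#' @param path file of tab-separated 0-based node-id pairs (see
#'   [write_edgelist()])
#' @param n_nodes total node count; `NULL` infers max(id) + 1
#' @return an undirected `igraph` graph
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  el <- as.matrix(read.table(path, header = FALSE,
                             colClasses = "integer")[, 1:2])
  if (is.null(n_nodes)) n_nodes <- max(el) + 1L
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  igraph::add_edges(g, t(el + 1L))
}
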