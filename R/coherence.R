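# Synchronization observables: global order parameter R, local order
# parameter r_i, effective coupling K k_i r_i, pairwise phase coherence C_ij,
# the weighted network of synchronization (WNS) built from it, its
# maximum-weight spanning skeleton, and cross link rank preservation (CLRP).

new_coherence_matrix <- function(W, provenance = character()) {
  diag(W) <- 1
  structure(W, class = c("coherence_matrix", class(matrix())),
            provenance = provenance)
}

#' @export
print.coherence_matrix <- function(x, ...) {
  n <- nrow(x)
  w <- upper_weights(x)
  cat(sprintf(
    "<coherence_matrix> %d nodes, %d pair weights in [%.3f, %.3f] (mean %.3f)\n",
    n, length(w), min(w), max(w), mean(w)))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  provenance:", paste(prov, collapse = ", "), "\n")
  invisible(x)
}

#' Global order parameter R
#'
#' Time average of the modulus of the population mean phasor,
#' R = < | (1/N) sum_j exp(i theta_j(t)) | >_t, in [0, 1]: 0 for an
#' incoherent population, 1 for full phase synchrony.
#'
#' @param rec a `phase_record`
#' @return a single number in [0, 1]
#' @export
global_order_parameter <- function(rec) {
  ph <- rec$phases
  if (is.null(ph) || nrow(ph) == 0) stop("empty phase record")
  mean(sqrt(rowMeans(cos(ph))^2 + rowMeans(sin(ph))^2))
}

#' Local order parameter r_i
#'
#' Per-node coherence of the k_i neighbors of node i:
#' r_i = < | (1/k_i) sum over neighbors j of exp(i theta_j(t)) | >_t.
#' Defines the effective coupling K k_i r_i through which node i feels the
#' network.
#'
#' @param rec a `phase_record`
#' @param net the substrate `igraph` graph (every node must have degree >= 1)
#' @return numeric vector of length n, entries in [0, 1]
#' @export
local_order_parameter <- function(rec, net) {
  ph <- rec$phases
  if (is.null(ph) || nrow(ph) == 0) stop("empty phase record")
  n <- igraph::vcount(net)
  if (ncol(ph) != n) stop("record and network node counts differ")
  k <- igraph::degree(net)
  if (any(k == 0)) stop("isolated node(s): local order parameter undefined")
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  cs <- as.matrix(cos(ph) %*% A)
  ss <- as.matrix(sin(ph) %*% A)
  colMeans(sqrt(cs^2 + ss^2)) / k
}

#' Effective coupling strength per node
#'
#' K k_i r_i: the coupling through which node i interacts with its (partially
#' coherent) neighborhood.  Hubs at equal local coherence feel a
#' proportionally stronger pull, which is why synchronization seeds there.
#'
#' @param K coupling strength
#' @param net substrate `igraph` graph
#' @param r per-node local order parameter, entries in [0, 1]
#' @return numeric vector K * degree * r
#' @export
effective_coupling <- function(K, net, r) {
  k <- igraph::degree(net)
  if (length(r) != length(k)) stop("r length must equal the node count")
  if (any(r < -1e-12 | r > 1 + 1e-12)) stop("r entries must lie in [0, 1]")
  K * k * r
}

#' Pairwise phase coherence (PPC) matrix — the WNS
#'
#' C_ij = | < exp(i (theta_i(t) - theta_j(t))) >_t | for every unordered node
#' pair: 1 for a phase-locked pair (any constant offset), near 0 for
#' independently drifting phases.  The full symmetric matrix is the weighted
#' network of synchronization (WNS): the complete functional graph whose link
#' weights are the PPC values.
#'
#' @param rec a `phase_record`
#' @param id provenance label stored on the result (defaults to a summary of
#'   the run parameters)
#' @return a `coherence_matrix`: symmetric, unit diagonal, entries in [0, 1]
#' @export
pairwise_phase_coherence <- function(rec, id = NULL) {
  ph <- rec$phases
  if (is.null(ph) || nrow(ph) == 0) stop("empty phase record")
  s <- nrow(ph)
  cm <- cos(ph); sm <- sin(ph)
  re <- (crossprod(cm) + crossprod(sm)) / s
  im <- (crossprod(sm, cm) - crossprod(cm, sm)) / s
  W <- pmin(sqrt(re^2 + im^2), 1)
  if (is.null(id))
    id <- sprintf("run(K=%g, D=%g, seed=%s)", rec$K, rec$D,
                  if (is.null(rec$seed)) "<stream>" else format(rec$seed))
  new_coherence_matrix(W, provenance = id)
}

#' Average several WNS matrices element-wise
#'
#' Averaging the PPC over independent initial configurations suppresses the
#' configuration-specific component of the functional weights and sharpens
#' the physical/non-physical separation used for reconstruction.
#'
#' @param matrices a list of `coherence_matrix` objects of equal size
#' @return a `coherence_matrix` with concatenated provenance
#' @export
average_wns <- function(matrices) {
  if (length(matrices) < 1) stop("need at least one matrix")
  lapply(matrices, stop_if_not_wns)
  ns <- vapply(matrices, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("matrices differ in size")
  W <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  new_coherence_matrix(W, provenance = unlist(lapply(matrices,
                                                     attr, "provenance")))
}

#' Synchronization skeleton: maximum-weight spanning tree of the WNS
#'
#' The tree on all n nodes maximizing the summed PPC — the backbone along
#' which synchronization is organized.
#'
#' @param wns a `coherence_matrix`
#' @return a `skeleton_tree`: list with an `edges` tibble (`node_a`,
#'   `node_b`, `weight`) of n - 1 rows and `total_weight`
#' @export
skeleton <- function(wns) {
  stop_if_not_wns(wns)
  n <- nrow(wns)
  if (n < 2) stop("need at least two nodes")
  W <- unclass(wns)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tr <- igraph::mst(g, weights = -igraph::E(g)$weight)
  el <- igraph::as_edgelist(tr, names = FALSE)
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  o <- order(a, b)
  edges <- tibble::tibble(node_a = a[o], node_b = b[o],
                          weight = W[cbind(a, b)][o])
  structure(list(edges = edges, total_weight = sum(edges$weight),
                 n_nodes = n), class = "skeleton_tree")
}

#' @export
print.skeleton_tree <- function(x, ...) {
  cat(sprintf("<skeleton_tree> %d nodes, %d edges, total weight %.4f\n",
              x$n_nodes, nrow(x$edges), x$total_weight))
  invisible(x)
}

# Dense rank of links by descending weight, ties broken by link index.
link_ranks <- function(W) {
  w <- upper_weights(W)
  r <- integer(length(w))
  r[order(-w, seq_along(w))] <- seq_along(w)
  r
}

#' Cross link rank preservation (CLRP) between two WNSs
#'
#' Ranks all L = n(n-1)/2 links of each WNS by weight (rank 1 = heaviest,
#' ties broken by link index) and averages the per-link preservation
#' P_alpha = 1 - |rank_A - rank_B| / L.  1 means identical link orderings;
#' independent random orderings give about 2/3.
#'
#' @param wns_a,wns_b `coherence_matrix` objects of equal size
#' @return a single number in (0, 1]
#' @export
clrp <- function(wns_a, wns_b) {
  stop_if_not_wns(wns_a); stop_if_not_wns(wns_b)
  if (nrow(wns_a) != nrow(wns_b)) stop("matrices differ in size")
  ra <- link_ranks(wns_a); rb <- link_ranks(wns_b)
  L <- length(ra)
  mean(1 - abs(ra - rb) / L)
}

#' Mean PPC split by physical connection
#'
#' @param wns a `coherence_matrix`
#' @param net the substrate (truth) `igraph` graph
#' @return a tibble with one row per pair type (`connected`, `disconnected`):
#'   mean and standard deviation of the weights and the pair count
#' @export
coherence_by_connection <- function(wns, net) {
  stop_if_not_wns(wns)
  n <- nrow(wns)
  if (igraph::vcount(net) != n) stop("network and WNS node counts differ")
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  ut <- upper.tri(wns)
  w <- unclass(wns)
  tibble::tibble(
    pair_type = c("connected", "disconnected"),
    mean = c(mean(w[ut & A == 1]), mean(w[ut & A == 0])),
    sd = c(sd(w[ut & A == 1]), sd(w[ut & A == 0])),
    n_pairs = c(sum(ut & A == 1), sum(ut & A == 0))
  )
}

#' Mean PPC binned by degree product
#'
#' Averages C_ij over all pairs falling in logarithmic bins of the degree
#' product k_i * k_j — after the synchronization onset the heaviest-degree
#' pairs cohere first and the binned means increase with the bin value.
#'
#' @param wns a `coherence_matrix`
#' @param net the substrate `igraph` graph
#' @param bins_per_decade logarithmic bin density
#' @return a tibble with the bin's geometric midpoint `degree_product`,
#'   `mean_coherence`, and `n_pairs`
#' @export
coherence_by_degree_product <- function(wns, net, bins_per_decade = 4) {
  stop_if_not_wns(wns)
  n <- nrow(wns)
  if (igraph::vcount(net) != n) stop("network and WNS node counts differ")
  k <- igraph::degree(net)
  pairs <- link_pairs(n)
  kp <- k[pairs$node_a] * k[pairs$node_b]
  w <- upper_weights(wns)
  breaks <- 10^seq(floor(log10(min(kp))), ceiling(log10(max(kp))),
                   by = 1 / bins_per_decade)
  bin <- cut(kp, breaks = breaks, include.lowest = TRUE)
  mids <- sqrt(breaks[-length(breaks)] * breaks[-1])
  tibble::tibble(degree_product = mids[as.integer(bin)],
                 coherence = w) |>
    dplyr::group_by(.data$degree_product) |>
    dplyr::summarise(mean_coherence = mean(.data$coherence),
                     n_pairs = dplyr::n(), .groups = "drop")
}

#' Write a WNS as a dense symmetric TSV matrix
#' @param wns a `coherence_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_wns <- function(wns, path) {
  stop_if_not_wns(wns)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# netsync coherence_matrix n=%d", nrow(wns)), con)
  write.table(format(unclass(wns), digits = 17, trim = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read a WNS written by [write_wns()]
#' @param path input file path
#' @return a `coherence_matrix`
#' @export
read_wns <- function(path) {
  W <- as.matrix(read.table(path, header = FALSE, comment.char = "#",
                            sep = "\t"))
  dimnames(W) <- NULL
  new_coherence_matrix(W, provenance = path)
}

#' Export WNS link weights as an edge list
#'
#' Writes `node_a<TAB>node_b<TAB>weight` lines (0-based ids, smaller first)
#' for all pairs or only the `top_l` heaviest.
#'
#' @param wns a `coherence_matrix`
#' @param path output file path
#' @param top_l keep only the L heaviest links; `NULL` writes all pairs
#' @return `path`, invisibly
#' @export
write_wns_edgelist <- function(wns, path, top_l = NULL) {
  stop_if_not_wns(wns)
  pairs <- link_pairs(nrow(wns))
  w <- upper_weights(wns)
  o <- order(-w, seq_along(w))
  if (!is.null(top_l)) {
    if (top_l < 1 || top_l > length(w)) stop("top_l out of range")
    o <- o[seq_len(top_l)]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(pairs$node_a[o] - 1L, pairs$node_b[o] - 1L,
                   format(w[o], digits = 17, trim = TRUE), sep = "\t"), con)
  invisible(path)
}
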