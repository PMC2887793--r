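# Reconstruction of the physical network from an (averaged) WNS: links whose
# weights exceed a threshold are predicted physical; the threshold comes from
# the antimode of the bimodal all-pairs weight distribution; performance is
# scored by ROC/AUC over all n(n-1)/2 node pairs.

truth_labels <- function(net, n) {
  if (igraph::vcount(net) != n) stop("network and WNS node counts differ")
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  A[upper.tri(A)] == 1
}

#' Confusion counts of a thresholded reconstruction
#'
#' Pairs with weight strictly greater than `threshold` are predicted physical;
#' counts are over all unordered node pairs against the truth graph.
#'
#' @param wns a `coherence_matrix`
#' @param threshold weight cutoff (strict `>`)
#' @param truth the physical substrate as an `igraph` graph
#' @return a one-row tibble: `tp`, `fp`, `tn`, `fn`, `fpr`, `tpr`
#' @export
classify_links <- function(wns, threshold, truth) {
  stop_if_not_wns(wns)
  if (!is.finite(threshold)) stop("threshold must be finite")
  lab <- truth_labels(truth, nrow(wns))
  pred <- upper_weights(wns) > threshold
  tp <- sum(pred & lab); fp <- sum(pred & !lab)
  fn <- sum(!pred & lab); tn <- sum(!pred & !lab)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 fpr = fp / (tn + fp), tpr = tp / (tp + fn))
}

new_roc_curve <- function(tbl, auc, n_pos, n_neg) {
  structure(tbl, class = c("roc_curve", class(tbl)),
            auc = auc, n_pos = n_pos, n_neg = n_neg)
}

#' ROC curve of WNS-based link prediction
#'
#' Sweeps the prediction threshold through every distinct weight (ties
#' collapse to a single step) and emits the monotone (FPR, TPR) sequence from
#' (0, 0) to (1, 1).  Computed by a single sort and cumulative counts.
#'
#' @param wns a `coherence_matrix`
#' @param truth the physical substrate as an `igraph` graph (must have at
#'   least one connected and one disconnected pair)
#' @return a `roc_curve` tibble: `threshold`, `fpr`, `tpr`; the trapezoidal
#'   area is attached as attribute `auc` (see [auc()])
#' @export
roc_curve <- function(wns, truth) {
  stop_if_not_wns(wns)
  lab <- truth_labels(truth, nrow(wns))
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0)
    stop("degenerate truth: need both physical and non-physical pairs")
  w <- upper_weights(wns)
  o <- order(w, decreasing = TRUE)
  ws <- w[o]; ls <- lab[o]
  cum_tp <- cumsum(ls); cum_fp <- cumsum(!ls)
  last <- c(ws[-1] != ws[-length(ws)], TRUE) # last index of each tie group
  tbl <- tibble::tibble(
    threshold = c(Inf, ws[last]),
    fpr = c(0, cum_fp[last] / n_neg),
    tpr = c(0, cum_tp[last] / n_pos))
  new_roc_curve(tbl, auc = trapezoid_area(tbl$fpr, tbl$tpr),
                n_pos = n_pos, n_neg = n_neg)
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Area under a ROC curve
#'
#' Trapezoidal area of the (FPR, TPR) sweep.  Equals the probability that a
#' randomly chosen physical pair outweighs a randomly chosen non-physical
#' pair, with ties counted one half; 0.5 is the random-guessing baseline and
#' 1 a perfect reconstruction.
#'
#' @param roc a `roc_curve`
#' @return a single number in [0, 1]
#' @export
auc <- function(roc) {
  if (!inherits(roc, "roc_curve")) stop("expected a `roc_curve`")
  attr(roc, "auc")
}

#' ROC curve restricted to the L heaviest predicted links
#'
#' The prefix of the full ROC sweep whose thresholds admit at most `L`
#' predicted links (a tie group straddling L is excluded, keeping the strict
#' threshold semantics).
#'
#' @inheritParams roc_curve
#' @param L maximum number of predicted links, in [1, n(n-1)/2]
#' @return a `roc_curve` (attribute `auc` is the area of the truncated sweep)
#' @export
top_l_roc <- function(wns, truth, L) {
  stop_if_not_wns(wns)
  n_pairs <- nrow(wns) * (nrow(wns) - 1) / 2
  if (L < 1 || L > n_pairs) stop("L out of range [1, ", n_pairs, "]")
  full <- roc_curve(wns, truth)
  n_pred <- round(full$fpr * attr(full, "n_neg") +
                    full$tpr * attr(full, "n_pos"))
  keep <- n_pred <= L
  tbl <- tibble::as_tibble(full[keep, ])
  new_roc_curve(tbl, auc = trapezoid_area(tbl$fpr, tbl$tpr),
                n_pos = attr(full, "n_pos"), n_neg = attr(full, "n_neg"))
}

#' One-row summary of a ROC curve
#' @param x a `roc_curve`
#' @param ... unused
#' @return a one-row tibble: `auc`, `n_pos`, `n_neg`, `n_thresholds`
#' @exportS3Method generics::glance
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
                 n_neg = attr(x, "n_neg"), n_thresholds = nrow(x) - 1L)
}

#' Reconstruction threshold from the bimodal weight distribution
#'
#' Kernel-density smooths the distribution of all n(n-1)/2 link weights
#' (Gaussian kernel, rule-of-thumb bandwidth) and pairs the global density
#' mode with the secondary mode that is best separated from it: among all
#' other local maxima whose far side of the intervening antimode carries at
#' least `min_mass` of the weights, the one with the deepest relative valley
#' is chosen, and the antimode between the two is returned as the
#' threshold.  The mass requirement matters because physical links are a
#' small fraction (about `2/(n-1)`) of all pairs, so their mode is far
#' lighter than the non-physical bulk and must be distinguished from
#' zero-mass tail wiggles of the kernel estimate; the separation requirement
#' distinguishes it from sampling ripples of the bulk itself.  If no
#' secondary mode qualifies the distribution is flagged unimodal
#' (`bimodal = FALSE`) and the median weight returned with
#' `separation_quality = 0`.
#'
#' @param wns a `coherence_matrix`
#' @param bw kernel bandwidth rule or value, passed to [stats::density()]
#' @param n_grid density evaluation grid size
#' @param min_separation smallest antimode depth (relative to the lower of
#'   the two mode heights) accepted as genuine bimodality; shallower dips are
#'   treated as sampling wiggles of a unimodal density
#' @param min_mass smallest fraction of weights beyond the antimode for a
#'   secondary mode to count as a mode at all
#' @return a `threshold_estimate` list: `threshold`, `mode_lo`, `mode_hi`,
#'   `separation_quality` (depth of the antimode relative to the lower mode,
#'   in [0, 1]), `bimodal`
#' @export
bimodal_threshold <- function(wns, bw = "nrd0", n_grid = 512,
                              min_separation = 0.1, min_mass = 0.001) {
  stop_if_not_wns(wns)
  w <- upper_weights(wns)
  if (length(unique(w)) < 2) stop("need at least two distinct weights")
  d <- density(w, bw = bw, n = n_grid)
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1
  best <- NULL
  if (length(peak) >= 2) {
    g <- peak[which.max(y[peak])]
    for (p in setdiff(peak, g)) {
      valley <- if (p > g) seq(g, p) else seq(p, g)
      anti <- valley[which.min(y[valley])]
      sep <- 1 - y[anti] / min(y[g], y[p])
      mass <- if (p > g) mean(w > d$x[anti]) else mean(w < d$x[anti])
      if (mass < min_mass || sep < min_separation) next
      if (is.null(best) || sep > best$sep)
        best <- list(p = p, anti = anti, sep = sep)
    }
  }
  if (is.null(best)) {
    est <- list(threshold = median(w), mode_lo = NA_real_, mode_hi = NA_real_,
                separation_quality = 0, bimodal = FALSE)
  } else {
    est <- list(threshold = d$x[best$anti],
                mode_lo = d$x[min(g, best$p)], mode_hi = d$x[max(g, best$p)],
                separation_quality = best$sep,
                bimodal = TRUE)
  }
  structure(est, class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$bimodal) {
    cat(sprintf(
      "<threshold_estimate> bimodal: modes at %.3f / %.3f, antimode %.3f (separation %.2f)\n",
      x$mode_lo, x$mode_hi, x$threshold, x$separation_quality))
  } else {
    cat(sprintf("<threshold_estimate> unimodal: median fallback %.3f\n",
                x$threshold))
  }
  invisible(x)
}

#' Reconstruct the physical network by thresholding a WNS
#'
#' The inferred graph contains every pair whose weight strictly exceeds
#' `threshold`.
#'
#' @param wns a `coherence_matrix`
#' @param threshold weight cutoff (strict `>`)
#' @return an undirected `igraph` graph on the same nodes
#' @export
reconstruct <- function(wns, threshold) {
  stop_if_not_wns(wns)
  if (!is.finite(threshold)) stop("threshold must be finite")
  n <- nrow(wns)
  pairs <- link_pairs(n)
  keep <- upper_weights(wns) > threshold
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::add_edges(g, rbind(pairs$node_a[keep], pairs$node_b[keep]))
}
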