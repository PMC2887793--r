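# ggplot2 displays for the result types.

#' Plot a ROC curve
#'
#' @param object a `roc_curve`
#' @param ... unused
#' @return a ggplot object
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc")))
}

#' Plot order-parameter scaling curves
#'
#' Shows R (optionally rescaled by N^ratio) against coupling, one curve per
#' network size; at the right exponent ratio the curves cross at the critical
#' coupling.
#'
#' @param object a `scaling_curves` tibble
#' @param ratio exponent beta/nu used to rescale R to R * N^ratio
#' @param ... unused
#' @return a ggplot object
#' @exportS3Method ggplot2::autoplot
autoplot.scaling_curves <- function(object, ratio = 0, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      y = .data$R_mean * .data$N^ratio,
                      N = factor(.data$N))
  ylab <- if (ratio == 0) "R" else sprintf("R %s N^%.2f", "×", ratio)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$y,
                                   colour = .data$N)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Coupling strength K", y = ylab, colour = "N")
}

#' Plot the rescaled-curve crossing of a finite-size scaling fit
#'
#' @param object an `fss_fit`
#' @param ... unused
#' @return a ggplot object
#' @exportS3Method ggplot2::autoplot
autoplot.fss_fit <- function(object, ...) {
  autoplot.scaling_curves(object$curves, ratio = object$beta_over_nu) +
    ggplot2::geom_vline(xintercept = object$K_c, linetype = "dotted") +
    ggplot2::labs(title = sprintf("K_c = %.4f, beta/nu = %.2f",
                                  object$K_c, object$beta_over_nu))
}

#' Plot the all-pairs WNS weight distribution
#'
#' Kernel-density view of the link-weight distribution with the detected
#' modes and antimode threshold; optionally split by physical connection when
#' the truth graph is supplied.
#'
#' @param wns a `coherence_matrix`
#' @param truth optional substrate `igraph` graph for the split view
#' @param estimate optional [bimodal_threshold()] result to annotate
#' @return a ggplot object
#' @export
plot_weight_distribution <- function(wns, truth = NULL, estimate = NULL) {
  stop_if_not_wns(wns)
  w <- upper_weights(wns)
  if (is.null(truth)) {
    df <- tibble::tibble(weight = w, pair_type = "all")
  } else {
    lab <- truth_labels(truth, nrow(wns))
    df <- tibble::tibble(weight = w,
                         pair_type = ifelse(lab, "connected", "disconnected"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$weight,
                                        colour = .data$pair_type)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Link weight (PPC)", y = "Density", colour = NULL)
  if (!is.null(estimate))
    p <- p + ggplot2::geom_vline(xintercept = estimate$threshold,
                                 linetype = "dotted")
  p
}
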