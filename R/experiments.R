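# Ensemble experiment drivers: evolution of synchronization with coupling,
# robustness of the WNS over initial configurations (CLRP), reconstruction
# performance (ROC/AUC), and the impact of substrate heterogeneity.  Every
# run's seed derives deterministically from (master seed, substrate index,
# configuration index, coupling index), so plans re-run bit-identically and
# runs are independent.

#' Define an ensemble experiment plan
#'
#' @param model substrate family: `"ba"`, `"regular"` or `"cutoff"`
#' @param n_nodes network size
#' @param n_networks number of independent substrate networks
#' @param n_configs number of initial configurations per substrate
#' @param K_grid coupling strengths to scan
#' @param D,dt,t_transient,t_measure,stride simulation settings (see
#'   [simulate_phases()]); defaults are the desk-scale measurement window
#'   under which the pair-coherence time averages have converged
#' @param seed master seed
#' @param model_args extra generator arguments: `m` (ba), `k` (regular),
#'   `kappa`/`mean_degree` (cutoff)
#' @return an `experiment_plan` list
#' @export
experiment_plan <- function(model = c("ba", "regular", "cutoff"),
                            n_nodes = 512, n_networks = 3, n_configs = 3,
                            K_grid = c(0.002, 0.01, 0.02, 0.05, 0.14),
                            D = 0.01, dt = 0.01,
                            t_transient = 500, t_measure = 2000,
                            stride = 10L, seed = 1, model_args = list()) {
  model <- match.arg(model)
  stopifnot(n_networks >= 1, n_configs >= 1, all(K_grid >= 0))
  structure(list(model = model, n_nodes = n_nodes, n_networks = n_networks,
                 n_configs = n_configs, K_grid = K_grid, D = D, dt = dt,
                 t_transient = t_transient, t_measure = t_measure,
                 stride = as.integer(stride), seed = seed,
                 model_args = model_args),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf(
    "<experiment_plan> %s, n = %d: %d networks x %d configurations, %d K values\n",
    x$model, x$n_nodes, x$n_networks, x$n_configs, length(x$K_grid)))
  cat(sprintf("  D = %g, dt = %g, window %g + %g time units, seed = %d\n",
              x$D, x$dt, x$t_transient, x$t_measure, x$seed))
  invisible(x)
}

plan_substrate <- function(plan, s) {
  seed <- derive_seed(plan$seed, 1, s)
  a <- plan$model_args
  switch(plan$model,
    ba = generate_ba(plan$n_nodes, m = a$m %||% 2, seed = seed),
    regular = generate_regular(plan$n_nodes, k = a$k %||% 4, seed = seed),
    cutoff = generate_cutoff(plan$n_nodes, kappa = a$kappa,
                             mean_degree = a$mean_degree %||% 4, seed = seed))
}

plan_init <- function(plan, s, c) {
  draw_initial_configuration(plan$n_nodes, seed = derive_seed(plan$seed, 2, s, c))
}

plan_record <- function(plan, net, init, s, c, kk) {
  simulate_phases(net, K = plan$K_grid[kk], D = plan$D, dt = plan$dt,
                  t_transient = plan$t_transient, t_measure = plan$t_measure,
                  stride = plan$stride, init = init,
                  seed = derive_seed(plan$seed, 3, s, c, kk))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

summarise_metrics <- function(rows) {
  rows |>
    dplyr::group_by(.data$K, .data$metric, .data$bin) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = if (dplyr::n() > 1)
                       sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
                     n = dplyr::n(), .groups = "drop")
}

#' Evolution of synchronization with coupling strength
#'
#' For every coupling on the plan's grid and every (substrate, initial
#' configuration) pair: the global order parameter, mean PPC over physically
#' connected and disconnected pairs, mean PPC binned by degree product, and
#' the local order parameter binned by degree — ensemble-averaged with
#' standard errors.
#'
#' @param plan an [experiment_plan()]
#' @param metrics which observables to compute; dropping the binned metrics
#'   (`C_by_degree_product`, `r_by_degree`) skips the local-order-parameter
#'   pass and speeds up large scans
#' @return a tibble: `K`, `metric`, `bin` (degree product or degree for the
#'   binned metrics, `NA` for scalars), `mean`, `se`, `n`
#' @export
run_evolution_experiment <- function(plan,
                                     metrics = c("R", "C_connected",
                                                 "C_disconnected",
                                                 "C_by_degree_product",
                                                 "r_by_degree")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- list()
  for (s in seq_len(plan$n_networks)) {
    net <- plan_substrate(plan, s)
    deg <- igraph::degree(net)
    for (c in seq_len(plan$n_configs)) {
      init <- plan_init(plan, s, c)
      for (kk in seq_along(plan$K_grid)) {
        rec <- plan_record(plan, net, init, s, c, kk)
        wns <- pairwise_phase_coherence(rec)
        bc <- coherence_by_connection(wns, net)
        parts <- list(
          tibble::tibble(metric = "R", bin = NA_real_,
                         value = global_order_parameter(rec)),
          tibble::tibble(metric = "C_connected", bin = NA_real_,
                         value = bc$mean[bc$pair_type == "connected"]),
          tibble::tibble(metric = "C_disconnected", bin = NA_real_,
                         value = bc$mean[bc$pair_type == "disconnected"]))
        if ("C_by_degree_product" %in% metrics) {
          dp <- coherence_by_degree_product(wns, net)
          parts <- c(parts, list(tibble::tibble(
            metric = "C_by_degree_product",
            bin = dp$degree_product, value = dp$mean_coherence)))
        }
        if ("r_by_degree" %in% metrics) {
          r <- local_order_parameter(rec, net)
          rk <- tibble::tibble(k = deg, r = r) |>
            dplyr::group_by(.data$k) |>
            dplyr::summarise(r = mean(.data$r), .groups = "drop")
          parts <- c(parts, list(tibble::tibble(
            metric = "r_by_degree", bin = as.numeric(rk$k), value = rk$r)))
        }
        rows[[length(rows) + 1]] <- dplyr::bind_rows(parts) |>
          dplyr::mutate(K = plan$K_grid[kk], substrate = s, config = c)
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(K = numeric(), metric = character(),
                          bin = numeric(), mean = numeric(), se = numeric(),
                          n = integer()))
  }
  out <- summarise_metrics(dplyr::bind_rows(rows))
  out[out$metric %in% metrics, ]
}

#' Robustness of the WNS over substrates and initial configurations (CLRP)
#'
#' Builds one WNS per (substrate, configuration) cell at each requested
#' coupling and computes the full pairwise CLRP matrix across all cells.
#' Above the synchronization transition the intra-substrate blocks (same
#' graph, different initial configurations) approach 1 while inter-substrate
#' values stay at the random background.
#'
#' @param plan an [experiment_plan()] with at least 2 substrates and 2
#'   configurations
#' @param K_values couplings to evaluate (default: the plan's grid)
#' @return a tibble of all ordered cell pairs: `K`, `substrate_a`,
#'   `config_a`, `substrate_b`, `config_b`, `clrp`; summarize with
#'   [clrp_summary()]
#' @export
run_robustness_experiment <- function(plan, K_values = plan$K_grid) {
  if (plan$n_networks < 2 || plan$n_configs < 2)
    stop("need >= 2 substrates and >= 2 configurations")
  kk_map <- match(K_values, plan$K_grid)
  if (anyNA(kk_map)) stop("K_values must be on the plan's K_grid")
  cells <- tidyr::expand_grid(s = seq_len(plan$n_networks),
                              c = seq_len(plan$n_configs))
  out <- list()
  for (j in seq_along(K_values)) {
    kk <- kk_map[j]
    nets <- lapply(seq_len(plan$n_networks), plan_substrate, plan = plan)
    wns <- purrr::pmap(cells, function(s, c) {
      pairwise_phase_coherence(
        plan_record(plan, nets[[s]], plan_init(plan, s, c), s, c, kk))
    })
    m <- length(wns)
    idx <- which(upper.tri(diag(m), diag = TRUE), arr.ind = TRUE)
    vals <- vapply(seq_len(nrow(idx)), function(r) {
      clrp(wns[[idx[r, 1]]], wns[[idx[r, 2]]])
    }, numeric(1))
    out[[j]] <- tibble::tibble(
      K = K_values[j],
      substrate_a = cells$s[idx[, 1]], config_a = cells$c[idx[, 1]],
      substrate_b = cells$s[idx[, 2]], config_b = cells$c[idx[, 2]],
      clrp = vals)
  }
  dplyr::bind_rows(out)
}

#' Summarize a CLRP table into intra- and inter-substrate means
#'
#' @param tbl output of [run_robustness_experiment()]
#' @return a tibble per (K, comparison in intra/inter): `mean`, `se`, `n`
#'   (self-comparisons are excluded)
#' @export
clrp_summary <- function(tbl) {
  tbl |>
    dplyr::filter(!(.data$substrate_a == .data$substrate_b &
                      .data$config_a == .data$config_b)) |>
    dplyr::mutate(comparison = ifelse(.data$substrate_a == .data$substrate_b,
                                      "intra", "inter")) |>
    dplyr::group_by(.data$K, .data$comparison) |>
    dplyr::summarise(mean = mean(.data$clrp),
                     se = sd(.data$clrp) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}

#' Reconstruction performance versus coupling and averaging depth
#'
#' For every coupling on the plan's grid and every substrate: simulates
#' `max(config_counts)` initial configurations, averages the first M WNSs for
#' each M in `config_counts`, and scores the averaged WNS against the
#' substrate by full-curve AUC and by the AUC of the curve truncated to the
#' `top_l` heaviest predicted links.
#'
#' @param plan an [experiment_plan()]
#' @param config_counts averaging depths M; all must be <= `plan$n_configs`
#' @param top_l truncation for the partial ROC (capped at the pair count)
#' @return a tibble: `K`, `substrate`, `n_configs_averaged`, `auc`,
#'   `auc_top_l`, `top_l`
#' @export
run_reconstruction_experiment <- function(plan, config_counts = c(1, plan$n_configs),
                                          top_l = 2000) {
  if (max(config_counts) > plan$n_configs)
    stop("max(config_counts) exceeds the plan's n_configs")
  n_pairs <- plan$n_nodes * (plan$n_nodes - 1) / 2
  top_l <- min(top_l, n_pairs)
  rows <- list()
  for (s in seq_len(plan$n_networks)) {
    net <- plan_substrate(plan, s)
    for (kk in seq_along(plan$K_grid)) {
      wns <- lapply(seq_len(max(config_counts)), function(c) {
        pairwise_phase_coherence(
          plan_record(plan, net, plan_init(plan, s, c), s, c, kk))
      })
      for (m in config_counts) {
        avg <- average_wns(wns[seq_len(m)])
        rows[[length(rows) + 1]] <- tibble::tibble(
          K = plan$K_grid[kk], substrate = s, n_configs_averaged = m,
          auc = auc(roc_curve(avg, net)),
          auc_top_l = auc(top_l_roc(avg, net, top_l)),
          top_l = top_l)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Onset coupling of pairwise correlation between disconnected nodes
#'
#' Estimates the coupling at which the disconnected-pair mean PPC departs
#' from its weak-coupling baseline.  The default `"hinge"` method fits the
#' one-breakpoint segmented model `mean ~ a + b * max(0, K - c)` by least
#' squares over a fine grid of candidate breakpoints `c` and returns the
#' best breakpoint: the point where the flat baseline turns into a rise.
#' The `"3se"` method instead returns the first grid coupling whose mean
#' exceeds the `baseline_K` value by 3 pooled standard errors; it is kept
#' for reference but degenerates on large desk ensembles, where the pooled
#' standard error shrinks far below the slow deterministic drift of the
#' finite-window coherence baseline, so it fires long before the actual
#' onset.
#'
#' @param K coupling grid (one entry per summarized mean)
#' @param mean ensemble means at each K
#' @param se standard errors at each K (used by `"3se"` only)
#' @param baseline_K the weak-coupling reference point (default: smallest K)
#' @param method `"hinge"` (default) or `"3se"`
#' @return the onset coupling (a breakpoint for `"hinge"`, a grid value for
#'   `"3se"`; `NA` if `"3se"` never fires)
#' @export
onset_coupling <- function(K, mean, se = NULL, baseline_K = min(K),
                           method = c("hinge", "3se")) {
  method <- match.arg(method)
  o <- order(K)
  K <- K[o]; mean <- mean[o]
  if (method == "hinge") {
    if (length(K) < 4) stop("hinge onset needs at least 4 couplings")
    cand <- seq(min(K), max(K), length.out = 512)
    sse <- vapply(cand, function(c0) {
      x <- pmax(0, K - c0)
      r <- stats::lm.fit(cbind(1, x), mean)$residuals
      sum(r^2)
    }, numeric(1))
    return(cand[which.min(sse)])
  }
  se <- se[o]
  b <- which(K == baseline_K)
  if (length(b) != 1) stop("baseline_K must match exactly one K")
  thr <- mean[b] + 3 * sqrt(se^2 + se[b]^2)
  hit <- which(K > baseline_K & mean > thr)
  if (length(hit)) K[min(hit)] else NA_real_
}

#' Impact of substrate heterogeneity on synchronization and reconstruction
#'
#' Runs the coupling scan for each target degree heterogeneity sigma (0 maps
#' to the random regular graph; positive values to the cutoff family with
#' kappa calibrated by [calibrate_kappa()]) and summarizes the global order
#' parameter and the connected/disconnected mean PPC, the onset coupling of
#' the disconnected-pair PPC, reconstruction AUC, and the weight-distribution
#' threshold estimate at selected snapshot couplings.
#'
#' @param plan an [experiment_plan()]; its `model` field is overridden per
#'   sigma target
#' @param sigma_targets degree-sequence standard deviations to realize
#' @param snapshot_K couplings (on the plan grid) at which the all-pairs
#'   weight distribution of the configuration-averaged WNS is summarized
#' @return a tibble: `sigma`, `K`, `metric`, `mean`, `se`, `n`; metrics are
#'   `R`, `C_connected`, `C_disconnected`, `auc`, and at snapshot couplings
#'   `threshold` and `bimodal` (share of substrates with a bimodal weight
#'   distribution).  The per-sigma onset couplings are attached as attribute
#'   `"onset"`.
#' @export
run_heterogeneity_experiment <- function(plan, sigma_targets = c(0, 1.4, 3.0),
                                         snapshot_K = numeric(0)) {
  if (!all(snapshot_K %in% plan$K_grid))
    stop("snapshot_K must lie on the plan's K_grid")
  out <- list(); onset <- list()
  for (sig in sigma_targets) {
    sp <- plan
    if (sig == 0) {
      sp$model <- "regular"
      sp$model_args$k <- plan$model_args$mean_degree %||% 4
    } else {
      sp$model <- "cutoff"
      sp$model_args$kappa <- as.numeric(
        calibrate_kappa(sig, n_nodes = plan$n_nodes,
                        mean_degree = plan$model_args$mean_degree %||% 4))
    }
    rows <- list()
    snap <- list() # running WNS sums per (substrate, snapshot K)
    for (s in seq_len(sp$n_networks)) {
      net <- plan_substrate(sp, s)
      for (c in seq_len(sp$n_configs)) {
        init <- plan_init(sp, s, c)
        for (kk in seq_along(sp$K_grid)) {
          K <- sp$K_grid[kk]
          rec <- plan_record(sp, net, init, s, c, kk)
          wns <- pairwise_phase_coherence(rec)
          bc <- coherence_by_connection(wns, net)
          rows[[length(rows) + 1]] <- tibble::tibble(
            K = K, substrate = s, config = c,
            metric = c("R", "C_connected", "C_disconnected"),
            bin = NA_real_,
            value = c(global_order_parameter(rec),
                      bc$mean[bc$pair_type == "connected"],
                      bc$mean[bc$pair_type == "disconnected"]))
          if (K %in% snapshot_K) {
            key <- paste(s, kk)
            snap[[key]] <- if (is.null(snap[[key]])) unclass(wns)
                           else snap[[key]] + unclass(wns)
          }
        }
      }
      # per-substrate summaries of the configuration-averaged WNS
      for (kk in which(sp$K_grid %in% snapshot_K)) {
        key <- paste(s, kk)
        avg <- new_coherence_matrix(snap[[key]] / sp$n_configs)
        est <- bimodal_threshold(avg)
        rows[[length(rows) + 1]] <- tibble::tibble(
          K = sp$K_grid[kk], substrate = s, config = NA_integer_,
          metric = c("auc", "threshold", "bimodal"), bin = NA_real_,
          value = c(auc(roc_curve(avg, net)), est$threshold,
                    as.numeric(est$bimodal)))
      }
    }
    smry <- summarise_metrics(dplyr::bind_rows(rows)) |>
      dplyr::mutate(sigma = sig, .before = 1) |>
      dplyr::select(-"bin")
    disc <- smry[smry$metric == "C_disconnected", ]
    onset[[length(onset) + 1]] <- tibble::tibble(
      sigma = sig,
      onset_K = if (length(unique(disc$K)) >= 4)
        onset_coupling(disc$K, disc$mean, disc$se) else NA_real_)
    out[[length(out) + 1]] <- smry
  }
  res <- dplyr::bind_rows(out)
  attr(res, "onset") <- dplyr::bind_rows(onset)
  res
}

#' Write a tidy result table as TSV
#' @param tbl a tibble
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_result_table <- function(tbl, path) {
  df <- as.data.frame(tbl)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
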