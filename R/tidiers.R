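#' Tidy a composite module into its member table
#'
#' @param x A `composite_module` from [run_cma()].
#' @param ... Unused.
#' @return Tibble with one row per member (`pwm_id`, `cutoff`, `weight`).
#' @method tidy composite_module
#' @export
tidy.composite_module <- function(x, ...) {
  x$members
}

#' One-row summary of a composite module
#'
#' @param x A `composite_module`.
#' @param ... Unused.
#' @return Tibble with `n_members`, `window`, `fitness`, `p_value`,
#'   `auc`, `critical_value`, `fp_rate`, `fn_rate`.
#' @method glance composite_module
#' @export
glance.composite_module <- function(x, ...) {
  tibble::tibble(n_members = nrow(x$members), window = x$window,
                 fitness = x$fitness, p_value = x$p_value, auc = x$auc,
                 critical_value = x$critical_value, fp_rate = x$fp_rate,
                 fn_rate = x$fn_rate)
}

#' Yes/No composite-score histograms for a module
#'
#' The classic diagnostic view: overlaid score distributions of the Yes
#' and No promoters with the critical value marked.
#'
#' @param object A `composite_module`.
#' @param bins Histogram bins (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composite_module
#' @export
autoplot.composite_module <- function(object, bins = 40, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$yes_scores, set = "Yes"),
    dplyr::mutate(object$no_scores, set = "No"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$composite_score,
                                   fill = .data$set)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity",
                            bins = bins) +
    ggplot2::geom_vline(xintercept = object$critical_value,
                        linetype = "dashed") +
    ggplot2::labs(x = "Composite score", y = "Promoters", fill = NULL,
                  title = sprintf("AUC %.3f, critical value %.2f",
                                  object$auc, object$critical_value)) +
    ggplot2::theme_minimal()
}

#' GA convergence trace of a composite-module search
#'
#' @param module A `composite_module`.
#' @return A ggplot of best and mean fitness by generation.
#' @export
plot_ga_trace <- function(module) {
  tr <- tidyr::pivot_longer(module$trace, c("best_fitness", "mean_fitness"),
                            names_to = "which", values_to = "fitness")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   linetype = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "-log10 Wilcoxon p",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy an IC50 fit
#'
#' @param x An `ic50_fit` from [fit_probit_ic50()].
#' @param ... Unused.
#' @return One-row tibble with `ic50`, `se`, `slope`, `intercept`.
#' @method tidy ic50_fit
#' @export
tidy.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, se = x$se, slope = x$slope,
                 intercept = x$intercept)
}

#' One-row summary of an IC50 fit
#'
#' @param x An `ic50_fit`.
#' @param ... Unused.
#' @return Tibble with `ic50`, `se`, `slope`, `n`, `converged`, `link`.
#' @method glance ic50_fit
#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, se = x$se, slope = x$slope, n = x$n,
                 converged = x$converged, link = x$link)
}

#' Dose-response curve with the fitted probit model
#'
#' @param object An `ic50_fit`.
#' @param ... Unused.
#' @return A ggplot of observed viable fractions and the fitted curve on
#'   a log10 concentration axis, with the IC50 marked.
#' @method autoplot ic50_fit
#' @export
autoplot.ic50_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    concentration_uM = 10^seq(log10(min(d$concentration_uM)),
                              log10(max(d$concentration_uM)),
                              length.out = 200))
  eta <- object$intercept + object$slope * log10(grid$concentration_uM)
  grid$fraction_alive <- 1 - (if (object$link == "probit") pnorm(eta)
                              else stats::plogis(eta))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_uM,
                                  y = .data$fraction_alive)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (uM)", y = "Fraction alive",
                  title = sprintf("IC50 = %.2f uM", object$ic50)) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of per-matrix enrichment
#'
#' @param enrichment Tibble from [run_fmatch()].
#' @return A ggplot of log2 Yes/No ratio versus -log10 p, passed
#'   matrices highlighted.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = log2(.data$ratio),
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$passed)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log2 Yes/No ratio", y = "-log10 p",
                  colour = "Passed") +
    ggplot2::theme_minimal()
}

#' Running-sum profile of a gene-set enrichment
#'
#' @param ranked Ranked tibble (`gene`, `weight`).
#' @param gene_set Character vector of member genes.
#' @return A ggplot of the running enrichment statistic.
#' @export
plot_running_sum <- function(ranked, gene_set) {
  prof <- enrichment_score(ranked, gene_set)
  df <- tibble::tibble(rank = seq_along(prof$running),
                       running = prof$running)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey") +
    ggplot2::labs(x = "Rank", y = "Running enrichment",
                  title = sprintf("ES = %.3f", prof$es)) +
    ggplot2::theme_minimal()
}
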