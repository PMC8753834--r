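#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the foreground/background running curves of one enrichment
#'
#' @param object A `histosig_enrichment` from [running_enrichment()].
#' @param ... Unused.
#' @return A ggplot: `f(i)` and `b(i)` against rank, with the position of
#'   maximum deviation marked.
#' @export
autoplot.histosig_enrichment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("f", "b"),
    names_to = "curve", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$i, y = .data$value, colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$i_star, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(f = "#D55E00", b = "#0072B2"),
      labels = c(f = "foreground f(i)", b = "background b(i)")
    ) +
    ggplot2::labs(
      x = "rank i (decreasing expression)", y = "cumulative weighted mass",
      colour = NULL,
      subtitle = sprintf("raw enrichment %.3f at i* = %d", object$es_raw, object$i_star)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `histosig_roc` from [response_classification()].
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the AUC in the subtitle.
#' @export
autoplot.histosig_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      subtitle = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of dichotomized score groups
#'
#' @param groups Two-level grouping (e.g. from [dichotomize()]).
#' @param survival Data frame with `time` and `event` columns.
#' @return A ggplot of the two Kaplan-Meier curves with the log-rank p in
#'   the subtitle.
#' @export
plot_km <- function(groups, survival) {
  check_survival(survival)
  fit <- survival::survfit(
    survival::Surv(survival$time, survival$event) ~ g,
    data = data.frame(g = as.factor(groups))
  )
  km <- tibble::tibble(
    time = fit$time,
    surv = fit$surv,
    group = rep(sub("^g=", "", names(fit$strata)), fit$strata)
  )
  # prepend t = 0, S = 1 per stratum so the step starts at the origin
  km <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, group = unique(km$group)),
    km
  )
  lr <- logrank_test(groups, survival)
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time (months)", y = "survival probability", colour = NULL,
      subtitle = sprintf("log-rank p = %.2g", lr$p)
    ) +
    ggplot2::theme_minimal()
}

#' Scores against latent truth for synthetic cohorts
#'
#' Convenience diagnostic: scatter of cohort scores versus the latent
#' lepidic fraction with the Spearman correlation in the subtitle.
#'
#' @param score_table Output of [score_cohort()].
#' @param fractions Truth fractions tibble (`sample_id`, `lepidic`, ...).
#' @return A ggplot.
#' @export
plot_score_recovery <- function(score_table, fractions) {
  dat <- dplyr::inner_join(score_table, fractions, by = "sample_id")
  rc <- rank_correlation(dat$score, dat$lepidic)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lepidic, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE, colour = "#D55E00") +
    ggplot2::labs(
      x = "latent lepidic fraction", y = "L-score",
      subtitle = sprintf("Spearman rho = %.3f", rc$rho)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
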