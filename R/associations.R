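#' Dichotomize scores into high/low groups
#'
#' Splits samples at the cohort median (default) or at zero. The high
#' group is `score > cutoff`; values exactly at the cutoff go to the low
#' group, a deterministic and conservative tie rule for "high-score"
#' claims.
#'
#' @param scores Numeric vector (named or not) of per-sample scores.
#' @param method `"median"` or `"zero"`.
#' @return Factor with levels `low`, `high`, same length as `scores`.
#' @export
dichotomize <- function(scores, method = c("median", "zero")) {
  method <- match.arg(method)
  if (length(scores) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  cutoff <- if (method == "median") stats::median(scores) else 0
  if (method == "median" && all(scores == scores[[1L]])) {
    stop("all scores identical; median split impossible", call. = FALSE)
  }
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' @param groups Two-level grouping vector aligned to `survival` rows.
#' @param survival Data frame with columns `time` (> 0) and `event`
#'   (0 = censored, 1 = event).
#' @return One-row tibble: `statistic` (chi-square, 1 df), `p`, `n`,
#'   `n_events`.
#' @export
logrank_test <- function(groups, survival) {
  check_survival(survival)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("need exactly 2 non-empty groups", call. = FALSE)
  if (sum(survival$event) < 1L) stop("no events observed", call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(survival$time, survival$event) ~ g,
    data = data.frame(g = groups)
  )
  tibble::tibble(
    statistic = unname(sd$chisq),
    p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n = nrow(survival),
    n_events = sum(survival$event)
  )
}

#' Cox proportional-hazards regression on a score
#'
#' Fits `Surv(time, event) ~ score (+ covariates)` by partial likelihood.
#' The score enters continuously by default (one hazard ratio per unit of
#' score; standardize beforehand for HR per SD) or dichotomized; extra
#' covariates (e.g. binary age group, sex, stage) come from columns of
#' `survival`.
#'
#' @param scores Numeric score per sample, aligned to `survival` rows, or
#'   a factor of group labels.
#' @param survival Data frame with `time`, `event` and any covariate
#'   columns.
#' @param covariates Character vector of covariate column names in
#'   `survival` (optional).
#' @return Object of class `histosig_cox` wrapping the `coxph` fit; use
#'   [tidy.histosig_cox()] for the hazard-ratio table.
#' @export
cox_regression <- function(scores, survival, covariates = NULL) {
  check_survival(survival)
  n_events <- sum(survival$event)
  if (n_events == 0L) stop("no events observed; Cox model cannot be fit", call. = FALSE)
  n_terms <- 1L + length(covariates)
  if (n_events < 10L * n_terms) {
    warning("fewer than 10 events per fitted covariate; estimates may be unstable", call. = FALSE)
  }
  dat <- data.frame(
    time = survival$time, event = survival$event,
    score = scores, check.names = FALSE
  )
  for (cv in covariates) {
    if (!cv %in% names(survival)) stop("covariate not found: ", cv, call. = FALSE)
    dat[[cv]] <- survival[[cv]]
  }
  form <- stats::reformulate(c("score", covariates), response = "survival::Surv(time, event)")
  fit <- survival::coxph(form, data = dat)
  if (!is.null(fit$info) && any(grepl("infinite", fit$info))) {
    warning("possible complete separation in Cox fit", call. = FALSE)
  }
  structure(list(fit = fit, n = nrow(dat), n_events = n_events), class = "histosig_cox")
}

#' Tidy a Cox fit into a hazard-ratio table
#'
#' @param x A `histosig_cox` object.
#' @param ... Unused.
#' @return Tibble: `term`, `hr`, `ci_low`, `ci_high` (Wald 95%), `p`.
#' @export
tidy.histosig_cox <- function(x, ...) {
  sm <- summary(x$fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  tibble::tibble(
    term = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    ci_low = unname(ci[, "lower .95"]),
    ci_high = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"])
  )
}

#' One-row summary of a Cox fit
#'
#' @param x A `histosig_cox` object.
#' @param ... Unused.
#' @return Tibble: `n`, `n_events`, `concordance`, `logrank_p` (score
#'   test), `likelihood_ratio_p`.
#' @export
glance.histosig_cox <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    concordance = unname(sm$concordance[["C"]]),
    logrank_p = unname(sm$sctest[["pvalue"]]),
    likelihood_ratio_p = unname(sm$logtest[["pvalue"]])
  )
}

#' @export
print.histosig_cox <- function(x, ...) {
  cat("<Cox proportional-hazards fit> n =", x$n, " events =", x$n_events, "\n")
  print(tidy.histosig_cox(x))
  invisible(x)
}

#' Associate scores with binary genomic features
#'
#' For each feature (e.g. per-gene mutation, amplification or deletion
#' status) altered in at least `min_count` samples, compares the scores of
#' altered versus wild-type samples with a two-sided Wilcoxon rank-sum
#' test. Following the original procedure, p-values are unadjusted and
#' features with `p < alpha` are flagged significant; set `adjust = TRUE`
#' for a BH-corrected column instead.
#'
#' @param scores Named numeric vector of per-sample scores (names =
#'   sample ids) or unnamed vector aligned to `features` columns.
#' @param features Binary (0/1 or logical) feature x sample matrix with
#'   feature rownames and sample colnames.
#' @param min_count Minimum altered samples for a feature to be tested.
#'   Default 20.
#' @param alpha Significance threshold on the (unadjusted) p. Default 0.01.
#' @param adjust If `TRUE`, flag on BH-adjusted p instead.
#' @return Tibble: `feature_id`, `n_altered`, `n_wildtype`, `statistic`
#'   (Wilcoxon W for altered vs wild-type), `p`, `direction` (sign of
#'   median score difference, altered minus wild-type), `significant`.
#' @export
feature_association <- function(scores, features, min_count = 20, alpha = 0.01,
                                adjust = FALSE) {
  if (!is.matrix(features)) stop("features must be a matrix", call. = FALSE)
  fv <- features
  storage.mode(fv) <- "double"
  if (!all(fv %in% c(0, 1))) stop("features must be binary", call. = FALSE)
  if (!is.null(names(scores)) && !is.null(colnames(features))) {
    if (!all(colnames(features) %in% names(scores))) {
      stop("feature samples missing from scores", call. = FALSE)
    }
    scores <- scores[colnames(features)]
  } else if (length(scores) != ncol(features)) {
    stop("scores and feature columns are not aligned", call. = FALSE)
  }
  n_alt <- rowSums(fv)
  keep <- which(n_alt >= min_count & n_alt <= ncol(fv) - 2L)
  if (length(keep) == 0L) stop("no feature altered in at least ", min_count, " samples", call. = FALSE)

  res <- purrr::map_dfr(keep, function(i) {
    alt <- fv[i, ] == 1
    wt <- suppressWarnings(
      stats::wilcox.test(scores[alt], scores[!alt], alternative = "two.sided")
    )
    tibble::tibble(
      feature_id = rownames(fv)[i],
      n_altered = sum(alt),
      n_wildtype = sum(!alt),
      statistic = unname(wt$statistic),
      p = wt$p.value,
      direction = sign(stats::median(scores[alt]) - stats::median(scores[!alt]))
    )
  })
  if (adjust) res$fdr <- benjamini_hochberg(res$p)
  res$significant <- (if (adjust) res$fdr else res$p) < alpha
  dplyr::arrange(res, .data$p)
}

#' Spearman rank correlation of scores with a continuous outcome
#'
#' Used e.g. for drug sensitivity expressed as `-ln(IC50 + 1)` or `-AUC`,
#' where larger values mean more sensitive cell lines. Pairs with a
#' missing outcome are dropped.
#'
#' @param scores Numeric vector of scores.
#' @param y Numeric outcome aligned to `scores`; may contain NA.
#' @return One-row tibble: `rho`, `p` (two-sided), `n` pairs used.
#' @export
rank_correlation <- function(scores, y) {
  if (length(scores) != length(y)) stop("scores and y must align", call. = FALSE)
  ok <- !is.na(scores) & !is.na(y)
  if (sum(ok) < 5L) stop("need at least 5 complete pairs", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(scores[ok], y[ok], method = "spearman", alternative = "two.sided")
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' ROC curve and AUC for a binary response
#'
#' The AUC is the probability that a randomly chosen responder outscores a
#' randomly chosen non-responder, with ties counting one half — computed
#' through the rank-sum identity `AUC = U / (n1 * n0)`, so it agrees
#' exactly with the Wilcoxon statistic on every input. The curve is
#' evaluated at every distinct score threshold. A two-group Wilcoxon
#' rank-sum p accompanies the AUC.
#'
#' @param scores Numeric score per sample.
#' @param labels Binary response indicator (0/1, logical, or a two-level
#'   factor whose second level is the responder class).
#' @return Object of class `histosig_roc`: list with `auc`, `wilcoxon_p`,
#'   `n_responder`, `n_nonresponder` and `curve` (tibble `threshold`,
#'   `tpr`, `fpr`).
#' @export
response_classification <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels == 1L)
  if (length(scores) != length(labels)) stop("scores and labels must align", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)

  r <- rank(scores) # midranks: ties contribute 1/2 through the rank-sum
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  wt <- suppressWarnings(
    stats::wilcox.test(scores[labels == 1L], scores[labels == 0L])
  )

  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(scores[labels == 1L] >= t), 0)),
    fpr = c(0, vapply(thr, function(t) mean(scores[labels == 0L] >= t), 0))
  )
  structure(
    list(
      auc = auc, wilcoxon_p = wt$p.value,
      n_responder = n1, n_nonresponder = n0, curve = curve
    ),
    class = "histosig_roc"
  )
}

#' @export
print.histosig_roc <- function(x, ...) {
  cat(
    "<ROC> AUC =", format(x$auc, digits = 4),
    " (", x$n_responder, "responders /", x$n_nonresponder, "non-responders )",
    " Wilcoxon p =", format(x$wilcoxon_p, digits = 3), "\n"
  )
  invisible(x)
}

check_survival <- function(survival) {
  if (!all(c("time", "event") %in% names(survival))) {
    stop("survival table needs columns time and event", call. = FALSE)
  }
  if (any(survival$time <= 0)) stop("survival times must be > 0", call. = FALSE)
  if (!all(survival$event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  invisible(survival)
}
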