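pipeline_defaults <- function() {
  list(
    expression = NULL, # path to expression TSV (genes in rows)
    annotation = NULL, # path to sample_id/subtype TSV
    survival = NULL, # optional survival TSV (sample_id, time, event, ...)
    features = NULL, # optional binary feature TSV (features in rows)
    drug = NULL, # optional drug TSV (sample_id, sensitivity)
    response = NULL, # optional response TSV (sample_id, response)
    signatures = NULL, # directory holding <subtype>_signature.tsv (run_report)
    out_dir = ".",
    target_subtypes = c("lepidic", "solid"),
    trim_cap = 10,
    log_base = "natural",
    t_test = "student", # or "welch"
    n_perm = 1000,
    seed = 1,
    overlap_threshold = 0.5,
    dichotomize = "median", # or "zero"
    min_count = 20,
    alpha = 0.01
  )
}

#' Read and validate a pipeline configuration
#'
#' Configuration is a flat YAML file of the keys shown by
#' `str(histosig:::pipeline_defaults())`; unknown keys are rejected and
#' numeric parameters are range-checked. Values not present fall back to
#' the defaults.
#'
#' @param path Path to a YAML config file, or a named list.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  stopifnot(
    cfg$trim_cap > 0,
    cfg$n_perm >= 100,
    cfg$overlap_threshold > 0, cfg$overlap_threshold <= 1,
    cfg$min_count >= 1,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$t_test %in% c("student", "welch"),
    cfg$log_base %in% c("natural", "log10"),
    cfg$dichotomize %in% c("median", "zero")
  )
  cfg
}

#' Build subtype signatures from an expression cohort
#'
#' Runs differential expression for each target subtype and writes, per
#' subtype, a `<subtype>_differential.tsv` profile and a
#' `<subtype>_signature.tsv` weighted signature, plus a `manifest.yaml`
#' recording every resolved parameter and the seed (permutation scores
#' downstream are irreproducible without it).
#'
#' @param config Path to a YAML config or a config list (see
#'   [read_pipeline_config()]); needs `expression` and `annotation`.
#' @return Invisibly, a named list of the written signature paths.
#' @export
run_build <- function(config) {
  cfg <- read_pipeline_config(config)
  for (key in c("expression", "annotation")) {
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required", call. = FALSE)
    if (!file.exists(cfg[[key]])) stop("file not found for '", key, "': ", cfg[[key]], call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  x <- read_expression_table(cfg$expression)
  ann <- utils::read.table(cfg$annotation, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

  paths <- list()
  for (s in cfg$target_subtypes) {
    dp <- differential_expression(x, ann, s, var_equal = cfg$t_test == "student")
    utils::write.table(dp, file.path(cfg$out_dir, paste0(s, "_differential.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    sig <- build_weighted_signature(dp, trim_cap = cfg$trim_cap, log_base = cfg$log_base)
    p <- file.path(cfg$out_dir, paste0(s, "_signature.tsv"))
    write_signature(sig, p)
    paths[[s]] <- p
  }
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], file.path(cfg$out_dir, "manifest.yaml"))
  invisible(paths)
}

#' Score a cohort and run every configured association analysis
#'
#' Loads the signatures written by [run_build()] (from
#' `config$signatures`, defaulting to `out_dir`), scores the expression
#' cohort for each, and then runs whichever downstream analyses have
#' input tables configured: median-split log-rank + Cox on survival,
#' Wilcoxon feature association on a binary feature matrix, Spearman
#' correlation on drug sensitivity, ROC/AUC on response labels. Each
#' analysis writes one TSV; a `report_summary.txt` lists n, test,
#' statistic and p per analysis. Sections without inputs are skipped with
#' a notice.
#'
#' @param config Path to a YAML config or a config list; needs
#'   `expression` and signatures on disk.
#' @return Invisibly, the score table joined to available outcomes.
#' @export
run_report <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$expression)) stop("config key 'expression' is required", call. = FALSE)
  sig_dir <- cfg$signatures %||% cfg$out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  x <- read_expression_table(cfg$expression)
  summary_lines <- character()
  note <- function(...) {
    summary_lines <<- c(summary_lines, sprintf(...))
    message(sprintf(...))
  }

  scores <- tibble::tibble(sample_id = colnames(x))
  for (s in cfg$target_subtypes) {
    p <- file.path(sig_dir, paste0(s, "_signature.tsv"))
    if (!file.exists(p)) stop("signature not found: ", p, call. = FALSE)
    sig <- read_signature(p)
    st <- score_cohort(x, sig,
      n_perm = cfg$n_perm, base_seed = cfg$seed,
      min_overlap = cfg$overlap_threshold
    )
    scores[[paste0(s, "_score")]] <- st$score[match(scores$sample_id, st$sample_id)]
    note(
      "scored %d samples with the %s signature (n_perm = %d, seed = %d)",
      nrow(st), s, cfg$n_perm, cfg$seed
    )
  }
  utils::write.table(scores, file.path(cfg$out_dir, "scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  primary <- paste0(cfg$target_subtypes[[1L]], "_score")
  read_tsv_if <- function(path) {
    if (is.null(path)) {
      return(NULL)
    }
    if (!file.exists(path)) stop("configured file not found: ", path, call. = FALSE)
    utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }

  surv <- read_tsv_if(cfg$survival)
  if (is.null(surv)) {
    note("survival section skipped: no survival table configured")
  } else {
    m <- dplyr::inner_join(scores, surv, by = "sample_id")
    grp <- dichotomize(m[[primary]], cfg$dichotomize)
    lr <- logrank_test(grp, m)
    cx <- tidy(cox_regression(scale(m[[primary]])[, 1L], m))
    out <- dplyr::bind_rows(
      tibble::tibble(analysis = "logrank_median_split", statistic = lr$statistic, p = lr$p),
      tibble::tibble(analysis = "cox_per_sd", statistic = cx$hr, p = cx$p)
    )
    utils::write.table(out, file.path(cfg$out_dir, "survival_association.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    note(
      "survival: n = %d, log-rank chi2 = %.3f (p = %.3g); Cox HR per SD = %.3f (p = %.3g)",
      nrow(m), lr$statistic, lr$p, cx$hr, cx$p
    )
  }

  feat_path <- cfg$features
  if (is.null(feat_path)) {
    note("feature section skipped: no feature matrix configured")
  } else {
    fm <- as.matrix(utils::read.table(feat_path,
      header = TRUE, sep = "\t",
      row.names = 1L, check.names = FALSE
    ))
    sc <- stats::setNames(scores[[primary]], scores$sample_id)
    fa <- feature_association(sc, fm, min_count = cfg$min_count, alpha = cfg$alpha)
    utils::write.table(fa, file.path(cfg$out_dir, "feature_association.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    note(
      "features: %d tested, %d significant at p < %g",
      nrow(fa), sum(fa$significant), cfg$alpha
    )
  }

  drug <- read_tsv_if(cfg$drug)
  if (is.null(drug)) {
    note("drug section skipped: no drug table configured")
  } else {
    m <- dplyr::inner_join(scores, drug, by = "sample_id")
    rc <- rank_correlation(m[[primary]], m$sensitivity)
    utils::write.table(rc, file.path(cfg$out_dir, "drug_correlation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    note("drug: n = %d, Spearman rho = %.3f (p = %.3g)", rc$n, rc$rho, rc$p)
  }

  resp <- read_tsv_if(cfg$response)
  if (is.null(resp)) {
    note("response section skipped: no response table configured")
  } else {
    m <- dplyr::inner_join(scores, resp, by = "sample_id")
    roc <- response_classification(m[[primary]], m$response)
    utils::write.table(roc$curve, file.path(cfg$out_dir, "roc_curve.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    note(
      "response: AUC = %.3f, Wilcoxon p = %.3g (%d responders / %d non-responders)",
      roc$auc, roc$wilcoxon_p, roc$n_responder, roc$n_nonresponder
    )
  }

  writeLines(summary_lines, file.path(cfg$out_dir, "report_summary.txt"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)], file.path(cfg$out_dir, "manifest.yaml"))
  invisible(scores)
}
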