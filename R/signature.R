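#' Differential expression of one histologic subtype versus the rest
#'
#' Per-gene two-sample t-test of the target subtype's samples against all
#' other annotated samples. Positive t means higher expression in the
#' target subtype. Two-sided p-values; FDR by Benjamini-Hochberg over all
#' genes. Genes with zero pooled variance get `t = 0, p = 1` rather than
#' being dropped, so the profile stays aligned with the matrix.
#'
#' @param x Expression matrix (genes x samples, log scale).
#' @param annotation Data frame with columns `sample_id` and `subtype`.
#'   Every annotated sample must exist in `x`; only annotated samples are
#'   used.
#' @param target Subtype label whose samples form the foreground group.
#' @param var_equal Pooled-variance Student test (`TRUE`, default) or
#'   Welch (`FALSE`).
#' @return A tibble with columns `gene_id`, `t`, `p`, `fdr`,
#'   `target_subtype`, one row per gene.
#' @seealso [build_weighted_signature()] to turn the profile into a
#'   weighted signature.
#' @export
differential_expression <- function(x, annotation, target, var_equal = TRUE) {
  validate_expression_matrix(x)
  if (!all(c("sample_id", "subtype") %in% names(annotation))) {
    stop("annotation needs columns sample_id and subtype", call. = FALSE)
  }
  missing <- setdiff(annotation$sample_id, colnames(x))
  if (length(missing) > 0L) {
    stop("annotated samples absent from expression matrix: ",
      paste(utils::head(missing, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  in_target <- annotation$sample_id[annotation$subtype == target]
  in_rest <- annotation$sample_id[annotation$subtype != target]
  if (length(in_target) == 0L) stop("target subtype '", target, "' not found", call. = FALSE)
  if (length(in_target) < 2L || length(in_rest) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }

  g1 <- x[, in_target, drop = FALSE]
  g2 <- x[, in_rest, drop = FALSE]
  n1 <- ncol(g1)
  n2 <- ncol(g2)
  m1 <- rowMeans(g1)
  m2 <- rowMeans(g2)
  ss1 <- rowSums((g1 - m1)^2)
  ss2 <- rowSums((g2 - m2)^2)

  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- (ss1 + ss2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- ss1 / (n1 - 1)
    v2 <- ss2 / (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }

  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- !is.finite(tstat)
  tstat[degenerate] <- 0
  p[degenerate] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1) # keep p in (0, 1]

  tibble::tibble(
    gene_id = rownames(x),
    t = unname(tstat),
    p = unname(p),
    fdr = benjamini_hochberg(unname(p)),
    target_subtype = target
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (a validated front for
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Build a weighted signature from a differential profile
#'
#' Converts per-gene t and p into the paired weight vectors `w_plus`
#' (up-regulated in the target subtype) and `w_minus` (down-regulated):
#' the negative log p-value is taken on the side the t-statistic points to,
#' trimmed at `trim_cap` to tame extreme significance, and rescaled to
#' `[0, 1]`. With the defaults (natural log, cap 10, rescale by the cap)
#' `w_plus = min(-ln p, 10) / 10` when `t > 0`, so a gene saturates at
#' weight 1 once `p <= exp(-10)` (about 4.5e-5). Genes with `t = 0` carry
#' no weight.
#'
#' @param dp Differential profile from [differential_expression()] (needs
#'   columns `gene_id`, `t`, `p`).
#' @param trim_cap Positive cap on `-log p` before rescaling. Default 10.
#' @param log_base `"natural"` (default) or `"log10"`.
#' @param rescale `"cap"` (divide by `trim_cap`; weights comparable across
#'   signatures, default) or `"minmax"` (per-vector min-max to `[0, 1]`).
#' @return A signature tibble (`gene_id`, `w_plus`, `w_minus`) carrying
#'   `trim_cap` and `target_subtype` attributes.
#' @export
build_weighted_signature <- function(dp, trim_cap = 10,
                                     log_base = c("natural", "log10"),
                                     rescale = c("cap", "minmax")) {
  log_base <- match.arg(log_base)
  rescale <- match.arg(rescale)
  if (nrow(dp) == 0L) stop("empty differential profile", call. = FALSE)
  if (!is.numeric(trim_cap) || trim_cap <= 0) stop("trim_cap must be > 0", call. = FALSE)
  if (any(dp$p <= 0 | dp$p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)

  nlp <- if (log_base == "natural") -log(dp$p) else -log10(dp$p)
  nlp <- pmin(nlp, trim_cap)
  raw_plus <- ifelse(dp$t > 0, nlp, 0)
  raw_minus <- ifelse(dp$t < 0, nlp, 0)

  if (rescale == "cap") {
    w_plus <- raw_plus / trim_cap
    w_minus <- raw_minus / trim_cap
  } else {
    scale01 <- function(v) if (max(v) > min(v)) (v - min(v)) / (max(v) - min(v)) else v * 0
    w_plus <- scale01(raw_plus)
    w_minus <- scale01(raw_minus)
  }

  sig <- new_signature(
    tibble::tibble(gene_id = dp$gene_id, w_plus = w_plus, w_minus = w_minus),
    trim_cap = trim_cap,
    target_subtype = if ("target_subtype" %in% names(dp)) dp$target_subtype[[1L]] else NA_character_
  )
  validate_signature(sig)
  sig
}

#' Select the most subtype-specific genes across profiles
#'
#' Per profile, takes the `k` genes with the smallest p-value (ties broken
#' by larger `|t|`, then lexicographic gene id, so the choice is
#' deterministic) and returns the union across profiles. With the five
#' subtype profiles of a typical cohort and `k = 200` this yields up to
#' 1000 genes, the pool used for subtype-level ordination.
#'
#' @param profiles A single differential profile or a list of them.
#' @param k Genes to take per profile. Default 200.
#' @return Character vector of gene ids (sorted, duplicates merged).
#' @export
select_top_subtype_genes <- function(profiles, k = 200) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("need at least one profile", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  picked <- purrr::map(profiles, function(dp) {
    if (k > nrow(dp)) stop("k exceeds gene count in a profile", call. = FALSE)
    ord <- order(dp$p, -abs(dp$t), dp$gene_id)
    dp$gene_id[ord][seq_len(k)]
  })
  sort(unique(unlist(picked)))
}
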