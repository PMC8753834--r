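#' Rank a sample's genes by decreasing expression
#'
#' Stable decreasing sort of a named expression vector; ties are broken
#' lexicographically by gene id so the ranking is deterministic across
#' platforms. Ranking uses the signed values (negative two-channel log
#' ratios stay at the bottom); absolute values enter only the enrichment
#' curves themselves.
#'
#' @param expr Named numeric vector (names = gene ids) for one sample.
#' @return A tibble with columns `gene_id` and `e`, `e` non-increasing.
#' @export
rank_genes <- function(expr) {
  if (length(expr) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (is.null(names(expr)) || anyNA(names(expr))) stop("expression vector must be named", call. = FALSE)
  if (anyDuplicated(names(expr))) stop("duplicate gene ids", call. = FALSE)
  if (anyNA(expr)) stop("missing expression values", call. = FALSE)
  ord <- order(-expr, names(expr), method = "radix")
  tibble::tibble(gene_id = names(expr)[ord], e = unname(expr[ord]))
}

#' Running foreground/background enrichment of a weight vector
#'
#' Walks down the ranked expression vector accumulating the weighted
#' absolute expression mass of the signature (foreground, weights `w`)
#' against the complementary mass (background, weights `1 - w`):
#' `f(i) = sum_{k<=i} |e_k w_k| / sum_k |e_k w_k|` and `b(i)` likewise with
#' `1 - w_k`. The raw enrichment score is the signed deviation
#' `f(i*) - b(i*)` at the position `i*` of maximum absolute deviation
#' (smallest `i` on ties) — the GSEA running-sum convention. Positive
#' scores mean high-weight genes crowd the top of the ranking.
#'
#' @param ranked A ranked expression tibble from [rank_genes()].
#' @param w Numeric weights in `[0, 1]` aligned to `ranked` rows.
#' @return An object of class `histosig_enrichment`: a list with `curve`
#'   (tibble `i`, `gene_id`, `f`, `b`), `i_star` and `es_raw`.
#' @examples
#' r <- rank_genes(c(a = 4, b = 3, c = 2, d = 1))
#' running_enrichment(r, c(0, 1, 0, 1))$es_raw # -2/3
#' @export
running_enrichment <- function(ranked, w) {
  if (length(w) != nrow(ranked)) stop("weights must align with ranked genes", call. = FALSE)
  if (anyNA(w) || any(w < 0 | w > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  a <- abs(ranked$e)
  aw <- a * w
  tot_f <- sum(aw)
  tot_b <- sum(a) - tot_f
  if (tot_f <= 0) stop("degenerate weights: foreground mass is zero", call. = FALSE)
  if (tot_b <= 0) stop("degenerate weights: background mass is zero", call. = FALSE)
  f <- cumsum(aw) / tot_f
  b <- (cumsum(a) - cumsum(aw)) / tot_b
  dev <- f - b
  i_star <- which.max(abs(dev)) # first index on ties
  structure(
    list(
      curve = tibble::tibble(i = seq_along(f), gene_id = ranked$gene_id, f = f, b = b),
      i_star = i_star,
      es_raw = dev[[i_star]]
    ),
    class = "histosig_enrichment"
  )
}

#' @export
print.histosig_enrichment <- function(x, ...) {
  cat(
    "<running enrichment> n =", nrow(x$curve),
    " es_raw =", format(x$es_raw, digits = 4),
    " at i* =", x$i_star, "\n"
  )
  invisible(x)
}

# Signed enrichment scores for many weight-to-gene assignments at once.
# `a` is |e| in ranked order; `perm` an n x P matrix of gene indices, each
# column one reassignment of weights to ranks. Works in blocks so the
# cumulative-sum trick (one cumsum over the flattened block) never holds
# more than ~block_cols columns of doubles at a time.
null_enrichment_scores <- function(a, w, perm, block_cols = 256L) {
  n <- length(a)
  ca <- cumsum(a)
  tot_a <- ca[[n]]
  P <- ncol(perm)
  out <- numeric(P)
  for (start in seq(1L, P, by = block_cols)) {
    cols <- start:min(start + block_cols - 1L, P)
    aw <- a * matrix(w[perm[, cols, drop = FALSE]], nrow = n)
    cs <- sweep_block_cumsum(aw)
    tot_f <- cs[n, ]
    tot_b <- tot_a - tot_f
    dev <- cs / rep(tot_f, each = n) - (ca - cs) / rep(tot_b, each = n)
    out[cols] <- dev[cbind(max.col(t(abs(dev)), ties.method = "first"), seq_along(cols))]
  }
  out
}

# column-wise cumulative sums via one flat cumsum
sweep_block_cumsum <- function(m) {
  n <- nrow(m)
  cs <- matrix(cumsum(m), nrow = n)
  if (ncol(m) > 1L) {
    offset <- c(0, cs[n, -ncol(m)])
    cs <- cs - rep(offset, each = n)
  }
  cs
}

#' Normalize a raw enrichment score against its permutation null
#'
#' The null distribution is generated by uniformly random permutations of
#' the gene-to-weight assignment (the ranked expression stays fixed); the
#' returned score is the z-transform `(es_raw - mean_null) / sd_null`. A
#' null with zero spread (e.g. constant weights) is degenerate: the score
#' is 0 and the `degenerate` attribute is set.
#'
#' @param es_raw Raw enrichment score from [running_enrichment()].
#' @param ranked Ranked expression tibble.
#' @param w Weight vector aligned to `ranked`.
#' @param n_perm Number of permutations (>= 100). Default 1000.
#' @param seed Integer seed for the permutation stream (ignored when
#'   `perm` is given).
#' @param perm Optional pre-drawn n x n_perm index matrix, used to share
#'   one permutation stream across the two components of a score.
#' @return Normalized score (scalar) with attribute `degenerate`.
#' @export
permutation_normalize <- function(es_raw, ranked, w, n_perm = 1000, seed = NULL,
                                  perm = NULL) {
  if (is.null(perm)) {
    if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
    perm <- draw_permutations(nrow(ranked), n_perm, seed)
  }
  a <- abs(ranked$e)
  null_es <- null_enrichment_scores(a, w, perm)
  s <- stats::sd(null_es)
  if (!is.finite(s) || s == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure((es_raw - mean(null_es)) / s, degenerate = FALSE)
}

draw_permutations <- function(n, n_perm, seed = NULL) {
  draw <- function() vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Score one sample against a weighted signature
#'
#' Intersects the sample's genes with the signature, ranks by decreasing
#' expression, computes the raw enrichment of `w_plus` and of `w_minus`,
#' normalizes each against a shared permutation null, and returns
#' `score = s_plus - s_minus`. A higher score means a higher relative
#' abundance of the signature's target component (lepidic signature ->
#' L-score, solid signature -> S-score).
#'
#' Both components are normalized with the *same* permutation index
#' sequence, so swapping `w_plus` and `w_minus` negates the score exactly
#' and the difference is not blurred by independent Monte-Carlo noise.
#' A component whose weights are all zero (one-sided profiles, e.g.
#' immune marker sets) contributes a zero score rather than an error.
#'
#' @param expr Named numeric expression vector for one sample.
#' @param sig Weighted signature tibble.
#' @param n_perm Permutations for the null (>= 100). Default 1000.
#' @param seed Integer seed for the permutation stream.
#' @param min_overlap Minimum fraction of signature genes that must be
#'   present in the sample (default 0.5); a warning is issued below 0.8.
#' @return One-row tibble: `s_plus`, `s_minus`, `score`, `es_plus_raw`,
#'   `es_minus_raw`, `overlap_fraction`, `n_perm`, `seed`, `degenerate`.
#' @export
score_sample <- function(expr, sig, n_perm = 1000, seed = NULL, min_overlap = 0.5) {
  validate_signature(sig)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  genes <- intersect(names(expr), sig$gene_id)
  overlap <- length(genes) / nrow(sig)
  if (overlap < min_overlap) {
    stop(sprintf(
      "only %.0f%% of signature genes present (threshold %.0f%%)",
      100 * overlap, 100 * min_overlap
    ), call. = FALSE)
  }
  if (overlap < 0.8) {
    warning(sprintf("signature overlap is %.0f%%; scores may be unstable", 100 * overlap),
      call. = FALSE
    )
  }
  ranked <- rank_genes(expr[genes])
  idx <- match(ranked$gene_id, sig$gene_id)
  wp <- sig$w_plus[idx]
  wm <- sig$w_minus[idx]

  perm <- draw_permutations(nrow(ranked), n_perm, seed)
  # one-sided profiles (e.g. immune marker sets) carry weight on one
  # component only; the empty component contributes a zero score
  score_component <- function(w) {
    if (all(w == 0)) {
      return(list(es = 0, s = structure(0, degenerate = FALSE)))
    }
    es <- running_enrichment(ranked, w)$es_raw
    list(es = es, s = permutation_normalize(es, ranked, w, perm = perm))
  }
  plus <- score_component(wp)
  minus <- score_component(wm)
  es_p <- plus$es
  es_m <- minus$es
  s_plus <- plus$s
  s_minus <- minus$s

  degenerate <- isTRUE(attr(s_plus, "degenerate")) || isTRUE(attr(s_minus, "degenerate"))
  tibble::tibble(
    s_plus = as.numeric(s_plus),
    s_minus = as.numeric(s_minus),
    score = s_plus - s_minus, # refers to the freshly built columns
    es_plus_raw = es_p,
    es_minus_raw = es_m,
    overlap_fraction = overlap,
    n_perm = as.integer(n_perm),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    degenerate = degenerate
  )
}

#' Score every sample of a cohort
#'
#' Vectorized front for [score_sample()]. Each sample gets its own
#' deterministic permutation seed, `base_seed` plus the sample's position
#' in the *sorted* id list, so results do not depend on column order and a
#' cohort run is bit-reproducible from `base_seed`. A sample that fails
#' (e.g. insufficient signature overlap) yields an NA score row plus a
#' warning rather than aborting the cohort.
#'
#' @param x Expression matrix (genes x samples).
#' @param sig Weighted signature tibble.
#' @param n_perm Permutations per sample. Default 1000.
#' @param base_seed Integer base seed. Keep it below ~2^31 - n_samples.
#' @param min_overlap As in [score_sample()].
#' @return Tibble with one row per sample: `sample_id` plus the
#'   [score_sample()] columns.
#' @export
score_cohort <- function(x, sig, n_perm = 1000, base_seed = 1L, min_overlap = 0.5) {
  validate_expression_matrix(x)
  validate_signature(sig)
  ids <- colnames(x)
  seeds <- base_seed + match(ids, sort(ids))
  purrr::map2_dfr(ids, seeds, function(id, sd) {
    res <- tryCatch(
      score_sample(x[, id], sig, n_perm = n_perm, seed = sd, min_overlap = min_overlap),
      error = function(e) {
        warning("sample ", id, " not scored: ", conditionMessage(e), call. = FALSE)
        tibble::tibble(
          s_plus = NA_real_, s_minus = NA_real_, score = NA_real_,
          es_plus_raw = NA_real_, es_minus_raw = NA_real_,
          overlap_fraction = NA_real_, n_perm = as.integer(n_perm),
          seed = as.integer(sd), degenerate = NA
        )
      }
    )
    dplyr::bind_cols(tibble::tibble(sample_id = id), res)
  })
}

#' Infiltration-style scores for a set of weight profiles
#'
#' Applies the same scoring engine once per supplied profile — e.g.
#' immune-cell weight profiles (naive/memory B, CD4+/CD8+ T, NK, myeloid
#' cells) taken from an external source. The profiles themselves are
#' inputs; this package does not derive them.
#'
#' @param x Expression matrix (genes x samples).
#' @param profiles Named list of weighted-signature tibbles.
#' @param n_perm,base_seed,min_overlap Passed to [score_cohort()].
#' @return Tibble with `sample_id` and one score column per profile
#'   (profile names as column names). Empty profile list gives a
#'   zero-column result.
#' @export
infiltration_scores <- function(x, profiles, n_perm = 1000, base_seed = 1L,
                                min_overlap = 0.5) {
  if (length(profiles) == 0L) {
    return(tibble::tibble(sample_id = character()))
  }
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    stop("profiles must be a named list", call. = FALSE)
  }
  long <- purrr::imap_dfr(profiles, function(sig, nm) {
    score_cohort(x, sig, n_perm = n_perm, base_seed = base_seed, min_overlap = min_overlap) |>
      dplyr::transmute(sample_id = .data$sample_id, cell_type = nm, score = .data$score)
  })
  tidyr::pivot_wider(long, names_from = "cell_type", values_from = "score")
}
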