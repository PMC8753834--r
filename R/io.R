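#' Read a gene-by-sample expression table
#'
#' Reads a delimited text table (TSV or CSV, autodetected from the first
#' line) with one header row and one identifier column into a numeric
#' expression matrix. Values are assumed to be on a log-like scale
#' (log-intensity or log TPM); the package never re-transforms them.
#'
#' Duplicate gene rows are collapsed by keeping the row with the largest
#' row-mean (the same convention [collapse_probesets()] uses for probes).
#' Rows containing any missing value are dropped and the count is reported
#' via a message; downstream scoring is rank-based, so imputation would
#' inject artificial structure.
#'
#' @param path Path to a delimited text file.
#' @param orientation `"genes_in_rows"` (default; header = sample ids) or
#'   `"samples_in_rows"` (the transpose).
#' @return A numeric matrix, genes in rows, samples in columns, with unique
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\t3\t4"), tf)
#' read_expression_table(tf)
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("expression table not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = delim, check.names = FALSE,
    stringsAsFactors = FALSE, comment.char = "#", quote = "\""
  )
  if (ncol(df) < 2L) stop("expression table needs an id column plus data columns", call. = FALSE)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (orientation == "samples_in_rows") mat <- t(mat)

  n_missing <- sum(!stats::complete.cases(mat))
  if (n_missing > 0L) {
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    message("dropped ", n_missing, " row(s) with missing values")
  }
  if (nrow(mat) == 0L) stop("all rows dropped (missing values)", call. = FALSE)
  mat <- collapse_duplicate_rows(mat)
  validate_expression_matrix(mat)
  mat
}

# keep, per duplicated id, the row with the largest row-mean
collapse_duplicate_rows <- function(mat) {
  if (!anyDuplicated(rownames(mat))) {
    return(mat)
  }
  rm <- rowMeans(mat)
  ord <- order(rownames(mat), -rm)
  mat <- mat[ord, , drop = FALSE]
  mat[!duplicated(rownames(mat)), , drop = FALSE]
}

#' Validate an expression matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric matrix
#' with unique gene and sample ids, no missing values, and at least two
#' genes and two samples.
#'
#' @param x Candidate matrix, genes in rows.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids", call. = FALSE)
  if (anyNA(x)) stop("expression matrix contains missing values", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  invisible(x)
}

#' Collapse probe-level intensities to gene level
#'
#' @param values Numeric matrix of intensities, probes in rows (rownames =
#'   probe ids), samples in columns.
#' @param probe_to_gene Data frame with columns `probe_id` and `gene_id`.
#'   Probes absent from the map (or mapped to `NA`/empty gene) are dropped.
#' @param method `"max_intensity"` keeps, per gene, the single probe with
#'   the largest mean intensity across samples (the usual one-channel
#'   convention); `"average"` returns the per-sample mean across the gene's
#'   probes (the two-channel convention).
#' @return Gene-level numeric matrix (genes x samples).
#' @export
collapse_probesets <- function(values, probe_to_gene,
                               method = c("max_intensity", "average")) {
  method <- match.arg(method)
  stopifnot(is.matrix(values), is.numeric(values))
  if (!all(c("probe_id", "gene_id") %in% names(probe_to_gene))) {
    stop("probe_to_gene needs columns probe_id and gene_id", call. = FALSE)
  }
  map <- probe_to_gene[!is.na(probe_to_gene$gene_id) & probe_to_gene$gene_id != "", , drop = FALSE]
  if (anyDuplicated(map$probe_id)) stop("a probe maps to more than one gene", call. = FALSE)
  keep <- rownames(values) %in% map$probe_id
  if (!any(keep)) stop("no probe maps to a gene", call. = FALSE)
  values <- values[keep, , drop = FALSE]
  gene <- map$gene_id[match(rownames(values), map$probe_id)]

  if (method == "max_intensity") {
    pm <- rowMeans(values)
    ord <- order(gene, -pm)
    values <- values[ord, , drop = FALSE]
    gene <- gene[ord]
    out <- values[!duplicated(gene), , drop = FALSE]
    rownames(out) <- gene[!duplicated(gene)]
  } else {
    out <- rowsum(values, group = gene) / as.vector(table(gene)[sort(unique(gene))])
  }
  out[order(rownames(out)), , drop = FALSE]
}

#' Write a weighted signature to a TSV file
#'
#' Emits a three-column table (`gene_id`, `w_plus`, `w_minus`) preceded by
#' `#`-comment header lines recording the trim cap and target subtype, so a
#' signature file is self-describing. Weights are printed at full double
#' precision and round-trip exactly through [read_signature()].
#'
#' @param sig A weighted signature tibble (see [build_weighted_signature()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  validate_signature(sig)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# histosig weighted signature"),
    paste0("# trim_cap: ", format(attr(sig, "trim_cap"), digits = 17)),
    paste0("# target_subtype: ", attr(sig, "target_subtype") %||% "NA")
  ), con)
  utils::write.table(
    data.frame(
      gene_id = sig$gene_id,
      w_plus = format(sig$w_plus, digits = 17, trim = TRUE, scientific = FALSE),
      w_minus = format(sig$w_minus, digits = 17, trim = TRUE, scientific = FALSE)
    ),
    con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a weighted signature from a TSV file
#'
#' @param path Path written by [write_signature()] (or any three-column
#'   gene/w_plus/w_minus table with optional `# trim_cap:` /
#'   `# target_subtype:` comment headers).
#' @return A weighted signature tibble with `trim_cap` and `target_subtype`
#'   attributes; invariants are re-validated on read.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0L) {
      return(NA_character_)
    }
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[[1L]]))
  }
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE
  )
  if (!all(c("gene_id", "w_plus", "w_minus") %in% names(df))) {
    stop("signature file needs columns gene_id, w_plus, w_minus", call. = FALSE)
  }
  trim_cap <- suppressWarnings(as.numeric(get_field("trim_cap")))
  if (is.na(trim_cap)) trim_cap <- 10
  target <- get_field("target_subtype")
  sig <- new_signature(
    tibble::tibble(
      gene_id = as.character(df$gene_id),
      w_plus = as.numeric(df$w_plus),
      w_minus = as.numeric(df$w_minus)
    ),
    trim_cap = trim_cap,
    target_subtype = if (identical(target, "NA")) NA_character_ else target
  )
  validate_signature(sig)
  sig
}

new_signature <- function(tbl, trim_cap, target_subtype = NA_character_) {
  attr(tbl, "trim_cap") <- trim_cap
  attr(tbl, "target_subtype") <- target_subtype
  class(tbl) <- unique(c("histosig_signature", class(tbl)))
  tbl
}

#' Validate a weighted signature
#'
#' A valid signature has unique gene ids, both weights in `[0, 1]`, at most
#' one non-zero weight per gene (a gene is either up- or down-specific,
#' never both) and at least one strictly positive weight overall.
#'
#' @param sig Candidate signature tibble.
#' @return `sig`, invisibly, if valid.
#' @export
validate_signature <- function(sig) {
  if (!all(c("gene_id", "w_plus", "w_minus") %in% names(sig))) {
    stop("signature needs columns gene_id, w_plus, w_minus", call. = FALSE)
  }
  if (anyDuplicated(sig$gene_id)) stop("duplicate gene ids in signature", call. = FALSE)
  w <- c(sig$w_plus, sig$w_minus)
  if (anyNA(w)) stop("signature weights contain NA", call. = FALSE)
  if (any(w < 0 | w > 1)) stop("signature weights must lie in [0, 1]", call. = FALSE)
  if (any(pmin(sig$w_plus, sig$w_minus) > 0)) {
    stop("a gene cannot carry both w_plus > 0 and w_minus > 0", call. = FALSE)
  }
  if (all(w == 0)) stop("signature has no informative genes (all weights zero)", call. = FALSE)
  invisible(sig)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
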