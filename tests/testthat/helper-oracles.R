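# Independent brute-force oracles used across the suite.

# naive double-loop running enrichment: explicit summations, no cumsum
naive_enrichment <- function(e, w) {
  n <- length(e)
  f <- b <- numeric(n)
  tf <- tb <- 0
  for (k in seq_len(n)) {
    tf <- tf + abs(e[k] * w[k])
    tb <- tb + abs(e[k] * (1 - w[k]))
  }
  for (i in seq_len(n)) {
    sf <- sb <- 0
    for (k in seq_len(i)) {
      sf <- sf + abs(e[k] * w[k])
      sb <- sb + abs(e[k] * (1 - w[k]))
    }
    f[i] <- sf / tf
    b[i] <- sb / tb
  }
  d <- f - b
  i_star <- which.max(abs(d))
  list(f = f, b = b, i_star = i_star, es = d[i_star])
}

# exact two-sided Wilcoxon p by enumerating every assignment of group sizes
enum_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled)) # enumeration assumes no ties
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu))
}

# small deterministic expression fixture
tiny_matrix <- function(nr = 6, nc = 4, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(nr * nc), nr,
      dimnames = list(paste0("g", seq_len(nr)), paste0("s", seq_len(nc)))
    )
  })
  m
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v)) # full double precision
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
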