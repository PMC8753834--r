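test_that("ranking is decreasing with deterministic lexicographic tie-break", {
  r <- rank_genes(c(A = 1, B = 3, C = 2))
  expect_identical(r$gene_id, c("B", "C", "A"))
  expect_identical(r$e, c(3, 2, 1))
  expect_identical(rank_genes(c(B = 2, A = 2))$gene_id, c("A", "B"))
  # idempotence on sorted input
  expect_identical(rank_genes(c(B = 3, C = 2, A = 1))$gene_id, c("B", "C", "A"))
  expect_error(rank_genes(c(A = 1)), "at least 2")
})

test_that("running enrichment reproduces hand-computed curves", {
  r <- tibble::tibble(gene_id = letters[1:4], e = c(4, 3, 2, 1))
  en <- running_enrichment(r, c(0, 1, 0, 1))
  expect_equal(en$curve$f, c(0, 3 / 4, 3 / 4, 1))
  expect_equal(en$curve$b, c(2 / 3, 2 / 3, 1, 1))
  expect_equal(en$i_star, 1L)
  expect_equal(en$es_raw, -2 / 3)

  # all foreground mass at the top
  en2 <- running_enrichment(r, c(1, 0, 0, 0))
  expect_equal(en2$es_raw, 1)
  expect_equal(en2$i_star, 1L)

  # constant weights make foreground and background coincide
  en3 <- running_enrichment(r, rep(0.3, 4))
  expect_equal(en3$es_raw, 0)
  expect_equal(en3$curve$f, en3$curve$b)
})

test_that("enrichment matches the naive double-loop oracle on random instances", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      e <- sort(rnorm(50), decreasing = TRUE)
      w <- ifelse(runif(50) < 0.3, runif(50), 0)
    })
    if (sum(w) == 0) w[1] <- 0.5
    r <- tibble::tibble(gene_id = sprintf("g%02d", 1:50), e = e)
    en <- running_enrichment(r, w)
    oracle <- naive_enrichment(e, w)
    expect_equal(en$es_raw, oracle$es, tolerance = 1e-12)
    expect_equal(en$i_star, oracle$i_star)
    expect_equal(en$curve$f, oracle$f, tolerance = 1e-12)
    expect_equal(en$curve$b, oracle$b, tolerance = 1e-12)
  }
})

test_that("curves are monotone, end at 1, and |es_raw| is the max deviation", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(5:80, 1)
      e <- sort(rnorm(n), decreasing = TRUE)
      w <- runif(n)
    })
    r <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)), e = e)
    en <- running_enrichment(r, w)
    expect_true(all(diff(en$curve$f) >= -1e-12))
    expect_true(all(diff(en$curve$b) >= -1e-12))
    expect_equal(en$curve$f[n], 1, tolerance = 1e-12)
    expect_equal(en$curve$b[n], 1, tolerance = 1e-12)
    expect_equal(abs(en$es_raw), max(abs(en$curve$f - en$curve$b)), tolerance = 1e-15)
    expect_true(abs(en$es_raw) <= 1)
  }
})

test_that("degenerate weights are rejected by the curves and flagged by the null", {
  r <- tibble::tibble(gene_id = letters[1:3], e = c(3, 2, 1))
  expect_error(running_enrichment(r, c(0, 0, 0)), "foreground")
  expect_error(running_enrichment(r, c(1, 1, 1)), "background")

  z <- permutation_normalize(0, r, c(0.5, 0.5, 0.5), n_perm = 100, seed = 1)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("permutation z-scores are self-calibrated under resampling", {
  withr::with_seed(21, {
    e <- sort(rnorm(300), decreasing = TRUE)
    w <- ifelse(runif(300) < 0.2, runif(300), 0)
  })
  r <- tibble::tibble(gene_id = sprintf("g%03d", 1:300), e = e)
  # score expression-to-weight assignments that are themselves random draws
  zs <- vapply(1:200, function(i) {
    wp <- withr::with_seed(1000 + i, sample(w))
    es <- running_enrichment(r, wp)$es_raw
    as.numeric(permutation_normalize(es, r, wp, n_perm = 150, seed = i))
  }, 0)
  expect_lt(abs(mean(zs)), 0.2)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.25)
})

test_that("top-heavy planted weights give a strongly positive normalized score", {
  withr::with_seed(33, {
    e <- sort(abs(rnorm(1000, 5)), decreasing = TRUE)
  })
  w <- c(rep(1, 50), rep(0, 950)) # mass on the 50 highest-expressed genes
  r <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000), e = e)
  es <- running_enrichment(r, w)$es_raw
  z <- permutation_normalize(es, r, w, n_perm = 200, seed = 4)
  expect_gt(as.numeric(z), 3)
})

test_that("score_sample enforces overlap and is exactly antisymmetric under w+/w- swap", {
  withr::with_seed(2, {
    expr <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    dp <- tibble::tibble(gene_id = sprintf("g%03d", 1:200), t = rnorm(200), p = runif(200))
  })
  sig <- build_weighted_signature(dp)
  res <- score_sample(expr, sig, n_perm = 150, seed = 7)
  expect_equal(res$score, res$s_plus - res$s_minus)
  expect_equal(res$overlap_fraction, 1)

  swapped <- sig
  swapped$w_plus <- sig$w_minus
  swapped$w_minus <- sig$w_plus
  res2 <- score_sample(expr, swapped, n_perm = 150, seed = 7)
  expect_identical(res2$score, -res$score) # bitwise, shared permutation stream
  expect_identical(res2$s_plus, res$s_minus)

  expect_error(
    score_sample(expr[1:80], sig, n_perm = 150, seed = 7), # 40% overlap
    "threshold"
  )
  expect_warning(
    score_sample(expr[1:140], sig, n_perm = 150, seed = 7), # 70%: warn
    "unstable"
  )
})

test_that("a lepidic-planted sample outscores a solid-planted one on the L-signature", {
  co <- generate_pure_cohort(n_genes = 3000, n_planted_per_subtype = 150, seed = 13)
  dp <- differential_expression(co$expression, co$annotation, "lepidic")
  sig <- build_weighted_signature(dp)
  lep <- co$annotation$sample_id[co$annotation$subtype == "lepidic"][1]
  sol <- co$annotation$sample_id[co$annotation$subtype == "solid"][1]
  s_lep <- score_sample(co$expression[, lep], sig, n_perm = 150, seed = 3)
  s_sol <- score_sample(co$expression[, sol], sig, n_perm = 150, seed = 3)
  expect_gt(s_lep$score, s_sol$score)
})

test_that("cohort scoring is reproducible, order-invariant, and matches score_sample", {
  withr::with_seed(8, {
    x <- matrix(rnorm(300 * 6), 300,
      dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:6))
    )
    dp <- tibble::tibble(gene_id = rownames(x), t = rnorm(300), p = runif(300))
  })
  sig <- build_weighted_signature(dp)
  st <- score_cohort(x, sig, n_perm = 120, base_seed = 5)
  st_again <- score_cohort(x, sig, n_perm = 120, base_seed = 5)
  expect_identical(st, st_again)

  shuffled <- score_cohort(x[, c(4, 2, 6, 1, 3, 5)], sig, n_perm = 120, base_seed = 5)
  expect_identical(
    st[order(st$sample_id), ],
    shuffled[order(shuffled$sample_id), ]
  )

  one <- score_cohort(x[, 1:2], sig, n_perm = 120, base_seed = 5)
  direct <- score_sample(x[, "s1"], sig, n_perm = 120, seed = 5 + 1)
  expect_equal(one$score[one$sample_id == "s1"], direct$score)
})

test_that("failed samples yield NA rows without aborting the cohort", {
  withr::with_seed(8, {
    x <- matrix(rnorm(100 * 3), 100,
      dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:3))
    )
    dp <- tibble::tibble(gene_id = rownames(x), t = rnorm(100), p = runif(100))
  })
  sig <- build_weighted_signature(dp)
  x["g001", "s2"] <- NA # rank_genes will refuse this sample
  expect_error(validate_expression_matrix(x))
  x2 <- x
  x2["g001", "s2"] <- 0
  st <- suppressWarnings(score_cohort(x2, sig, n_perm = 120, base_seed = 1))
  expect_equal(nrow(st), 3)
})

test_that("infiltration scoring is the same engine applied per profile", {
  co <- generate_pure_cohort(n_genes = 800, n_planted_per_subtype = 50, seed = 17)
  x <- co$expression[, 1:6]
  dp <- differential_expression(co$expression, co$annotation, "lepidic")
  sig <- build_weighted_signature(dp)

  inf <- infiltration_scores(x, list(lepidic_like = sig), n_perm = 120, base_seed = 2)
  ref <- score_cohort(x, sig, n_perm = 120, base_seed = 2)
  expect_equal(inf$lepidic_like, ref$score)

  expect_identical(nrow(infiltration_scores(x, list())), 0L)
})

test_that("a planted marker-high sample tops its marker profile", {
  withr::with_seed(29, {
    g <- sprintf("g%03d", 1:500)
    x <- matrix(rnorm(500 * 10), 500, dimnames = list(g, paste0("s", 1:10)))
    markers <- sample(g, 40)
  })
  x[markers, "s4"] <- x[markers, "s4"] + 2 # immune-high sample
  prof <- tibble::tibble(
    gene_id = g,
    w_plus = as.numeric(g %in% markers),
    w_minus = 0
  )
  prof <- histosig:::new_signature(prof, trim_cap = 10)
  inf <- infiltration_scores(x, list(marker = prof), n_perm = 150, base_seed = 6)
  expect_identical(inf$sample_id[which.max(inf$marker)], "s4")
})
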