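test_that("dichotomization uses the deterministic at-cutoff-goes-low rule", {
  g <- dichotomize(c(-1, 0, 1, 2), "median") # median 0.5
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  gz <- dichotomize(c(-1, 0, 1, 2), "zero")
  expect_identical(as.character(gz), c("low", "low", "high", "high"))
  expect_error(dichotomize(rep(3, 4), "median"), "identical")
  # exact median value is assigned low
  g5 <- dichotomize(c(1, 2, 3, 4, 5), "median")
  expect_identical(as.character(g5), c("low", "low", "low", "high", "high"))
})

test_that("median split sizes are ceiling/floor of n/2 for distinct scores", {
  for (n in c(4, 5, 10, 11)) {
    withr::with_seed(n, s <- rnorm(n))
    g <- dichotomize(s, "median")
    expect_equal(sum(g == "low"), ceiling(n / 2))
    expect_equal(sum(g == "high"), floor(n / 2))
  }
})

test_that("log-rank test agrees with survdiff and is null on identical groups", {
  surv <- tibble::tibble(time = rep(c(5, 10, 15, 20), 2), event = rep(c(1, 0, 1, 1), 2))
  lr <- logrank_test(rep(c("a", "b"), each = 4), surv)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  withr::with_seed(4, {
    surv2 <- tibble::tibble(time = rexp(40, 0.1), event = rbinom(40, 1, 0.8))
  })
  grp <- rep(c("a", "b"), 20)
  lr2 <- logrank_test(grp, surv2)
  sd2 <- survival::survdiff(survival::Surv(surv2$time, surv2$event) ~ grp)
  expect_equal(lr2$statistic, unname(sd2$chisq), tolerance = 1e-12)
  # invariant to swapping group labels
  swapped <- logrank_test(rev(grp), surv2[nrow(surv2):1, ])
  expect_equal(lr2$statistic, swapped$statistic, tolerance = 1e-12)
})

test_that("log-rank has high power under a strong hazard ratio", {
  rejections <- vapply(1:30, function(i) {
    withr::with_seed(500 + i, {
      g <- rep(c(0, 1), each = 150)
      t_ev <- rexp(300, rate = 0.02 * 3^g) # true HR 3
      cens <- runif(300) < 0.2
      time <- ifelse(cens, runif(300) * t_ev, t_ev)
    })
    surv <- tibble::tibble(time = pmax(time, 1e-9), event = as.integer(!cens))
    logrank_test(g, surv)$p < 0.001
  }, NA)
  expect_gte(mean(rejections), 0.95)
})

test_that("a single event cannot produce strong log-rank evidence", {
  surv <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6), event = c(1, 0, 0, 0, 0, 0))
  p <- logrank_test(rep(c("a", "b"), 3), surv)$p
  expect_gte(p, 0.3)
})

test_that("Cox regression recovers a known hazard ratio and matches coxph", {
  withr::with_seed(9, {
    z <- rnorm(300)
    t_ev <- rexp(300, rate = 0.05 * exp(log(2) * z)) # HR 2 per SD
    cens <- runif(300) < 0.2
    time <- pmax(ifelse(cens, runif(300) * t_ev, t_ev), 1e-9)
  })
  surv <- tibble::tibble(time = time, event = as.integer(!cens))
  fit <- cox_regression(z, surv)
  td <- tidy(fit)
  expect_gt(td$hr, 1.6)
  expect_lt(td$hr, 2.5)
  ref <- survival::coxph(survival::Surv(time, surv$event) ~ z)
  expect_equal(log(td$hr), unname(coef(ref)), tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$n, 300)

  # covariate support
  surv$age_high <- as.integer(runif(300) > 0.5)
  fit2 <- cox_regression(z, surv, covariates = "age_high")
  expect_identical(tidy(fit2)$term, c("score", "age_high"))
  expect_error(cox_regression(z, surv, covariates = "nope"), "not found")
})

test_that("Cox CI covers the null HR at roughly the nominal rate", {
  covered <- vapply(1:60, function(i) {
    withr::with_seed(900 + i, {
      z <- rnorm(80)
      t_ev <- rexp(80, 0.05) # z unrelated to survival
      cens <- runif(80) < 0.2
      time <- pmax(ifelse(cens, runif(80) * t_ev, t_ev), 1e-9)
    })
    surv <- tibble::tibble(time = time, event = as.integer(!cens))
    td <- tidy(cox_regression(z, surv))
    td$ci_low <= 1 && td$ci_high >= 1
  }, NA)
  expect_gte(mean(covered), 0.85) # ~95% nominal, binomial noise at 60 reps
})

test_that("all-censored survival is rejected", {
  surv <- tibble::tibble(time = 1:10, event = rep(0, 10))
  expect_error(cox_regression(rnorm(10), surv), "no events")
  expect_error(logrank_test(rep(c("a", "b"), 5), surv), "no events")
})

test_that("feature association filters by count and reproduces the exact Wilcoxon p", {
  scores <- setNames(as.numeric(1:10), paste0("s", 1:10))
  features <- rbind(
    hit = c(1, 1, 1, rep(0, 7)), # alters the bottom 3 scores
    rare = c(1, 1, rep(0, 8)) # only 2 altered: filtered at min_count 3
  )
  colnames(features) <- names(scores)
  res <- feature_association(scores, features, min_count = 3, alpha = 0.05)
  expect_identical(res$feature_id, "hit")
  expect_equal(res$p, enum_wilcoxon_p(scores[1:3], scores[4:10]), tolerance = 1e-12)
  expect_equal(res$p, 2 / choose(10, 3), tolerance = 1e-12) # = 0.0167
  expect_equal(res$direction, -1)
})

test_that("boundary: a feature altered in exactly min_count - 1 samples is excluded", {
  withr::with_seed(3, scores <- setNames(rnorm(50), paste0("s", 1:50)))
  features <- rbind(
    below = c(rep(1, 19), rep(0, 31)),
    at = c(rep(1, 20), rep(0, 30))
  )
  colnames(features) <- names(scores)
  res <- feature_association(scores, features, min_count = 20)
  expect_identical(res$feature_id, "at")
  expect_error(feature_association(scores, features["below", , drop = FALSE], min_count = 20), "no feature")
})

test_that("Spearman correlation matches hand ranks and handles monotone extremes", {
  expect_equal(rank_correlation(1:6, c(2, 4, 6, 8, 10, 12))$rho, 1)
  expect_equal(rank_correlation(1:6, -(1:6))$rho, -1)
  # d = ranks diff, sum d^2 = 8 -> rho = 1 - 6*8/(5*24) = 0.6
  expect_equal(rank_correlation(1:5, c(3, 1, 2, 5, 4))$rho, 0.6, tolerance = 1e-12)
  expect_error(rank_correlation(1:4, c(1, 2, NA, 4)), "at least 5")
  # NA pairs dropped
  rc <- rank_correlation(1:6, c(2, 4, 6, 8, 10, NA))
  expect_equal(rc$n, 5)
})

test_that("AUC equals the rank-sum identity on arbitrary inputs including ties", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n <- sample(10:60, 1)
      scores <- sample(round(rnorm(n), 1)) # induce ties
      labels <- rbinom(n, 1, 0.4)
    })
    if (sum(labels) == 0 || sum(labels) == n) next
    roc <- response_classification(scores, labels)
    n1 <- sum(labels == 1)
    n0 <- sum(labels == 0)
    # independent route: pairwise comparison with half-credit ties
    auc_pairs <- mean(outer(scores[labels == 1], scores[labels == 0], ">") +
      0.5 * outer(scores[labels == 1], scores[labels == 0], "=="))
    expect_equal(roc$auc, auc_pairs, tolerance = 1e-12)
  }
})

test_that("ROC endpoints and degenerate inputs behave per the tie convention", {
  roc <- response_classification(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$auc, 1)
  expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)
  expect_equal(roc$curve$fpr[nrow(roc$curve)], 1)

  flat <- response_classification(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(flat$auc, 0.5)
  expect_error(response_classification(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  withr::with_seed(77, {
    scores <- rnorm(100)
    labels <- rbinom(100, 1, plogis(scores))
  })
  roc <- response_classification(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-12)
})
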