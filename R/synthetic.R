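#' Generate a pure-histology cohort with planted subtype-specific genes
#'
#' Emulates a microdissected design: each sample carries exactly one of
#' the five growth patterns, the default group sizes matching a typical
#' small cohort (10 acinar, 10 lepidic, 9 micropapillary, 9 papillary,
#' 10 solid). Baseline expression is iid Normal(0, `noise_sd`) on a
#' log-like scale; for each subtype, `n_planted_per_subtype` genes are
#' shifted by `effect_size` within-group SDs in that subtype's samples —
#' half up, half down.
#'
#' @param n_per_subtype Named integer vector of samples per subtype, all
#'   >= 2.
#' @param n_genes Total genes; must be at least 5x `n_planted_per_subtype`
#'   so planted sets stay disjoint with room for nulls. Default 10000.
#' @param n_planted_per_subtype Planted genes per subtype. Default 500.
#' @param effect_size Shift of planted genes in within-group SD units.
#'   Default 1.5.
#' @param noise_sd Within-group SD of expression. Default 1.
#' @param seed Integer seed; the cohort is bit-reproducible from it.
#' @return List with `expression` (matrix genes x samples), `annotation`
#'   (tibble `sample_id`, `subtype`), `truth` (see Details).
#'   `truth$genes` records each planted gene's subtype, direction
#'   (+1 up / -1 down) and effect size; `truth$params` the generator
#'   parameters.
#' @export
generate_pure_cohort <- function(n_per_subtype = c(
                                   acinar = 10, lepidic = 10,
                                   micropapillary = 9, papillary = 9, solid = 10
                                 ),
                                 n_genes = 10000, n_planted_per_subtype = 500,
                                 effect_size = 1.5, noise_sd = 1, seed = 1L) {
  if (is.null(names(n_per_subtype))) stop("n_per_subtype must be named", call. = FALSE)
  if (any(n_per_subtype < 2L)) stop("every subtype needs at least 2 samples", call. = FALSE)
  n_sub <- length(n_per_subtype)
  if (n_genes < 5L * n_planted_per_subtype) {
    stop("n_genes must be at least 5 x n_planted_per_subtype", call. = FALSE)
  }
  if (n_sub * n_planted_per_subtype > n_genes) {
    stop("planted genes exceed gene count", call. = FALSE)
  }

  withr::with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    subtypes <- rep(names(n_per_subtype), n_per_subtype)
    samples <- sprintf("s%03d", seq_along(subtypes))
    expr <- matrix(stats::rnorm(n_genes * length(samples), 0, noise_sd),
      nrow = n_genes, dimnames = list(genes, samples)
    )

    planted <- plant_roles(genes, names(n_per_subtype), n_planted_per_subtype, effect_size)
    for (s in names(n_per_subtype)) {
      rows <- planted$gene_id[planted$subtype == s]
      dir <- planted$direction[planted$subtype == s]
      cols <- samples[subtypes == s]
      expr[rows, cols] <- expr[rows, cols] + dir * effect_size * noise_sd
    }
  })

  list(
    expression = expr,
    annotation = tibble::tibble(sample_id = samples, subtype = subtypes),
    truth = list(
      genes = planted,
      params = list(
        n_per_subtype = n_per_subtype, n_genes = n_genes,
        n_planted_per_subtype = n_planted_per_subtype,
        effect_size = effect_size, noise_sd = noise_sd, seed = seed
      )
    )
  )
}

# disjoint planted gene sets, first half up, second half down, per subtype
plant_roles <- function(genes, subtypes, n_planted, effect_size) {
  picked <- sample(genes, length(subtypes) * n_planted)
  tibble::tibble(
    gene_id = picked,
    subtype = rep(subtypes, each = n_planted),
    direction = rep(rep(c(1, -1), length.out = n_planted), times = length(subtypes)),
    effect_size = effect_size
  )
}

#' Generate an admixed cohort with latent subtype fractions
#'
#' Emulates real tumors that mix growth patterns (e.g. 50% papillary, 30%
#' acinar, 20% lepidic): each sample's latent fraction vector is drawn
#' from a Dirichlet distribution and its expression is the
#' fraction-weighted mixture of the subtype mean profiles plus iid
#' Gaussian noise. Passing the `truth` of a pure cohort reuses its
#' planted gene structure, so signatures built on the pure cohort apply
#' directly to the admixed one.
#'
#' @param n_samples Number of samples (>= 1).
#' @param dirichlet_alpha Named positive vector of Dirichlet
#'   concentrations, one per subtype. Default: symmetric alpha = 1 over
#'   the five growth patterns.
#' @param truth Optional `truth` from [generate_pure_cohort()]; when
#'   `NULL`, a fresh planted structure is drawn.
#' @param n_genes,n_planted_per_subtype,effect_size,noise_sd As in
#'   [generate_pure_cohort()]; ignored (taken from `truth`) when `truth`
#'   is supplied.
#' @param seed Integer seed.
#' @return List with `expression` and `truth`; `truth$fractions` is a
#'   tibble (`sample_id`, one column per subtype) whose rows sum to 1.
#' @export
generate_admixed_cohort <- function(n_samples,
                                    dirichlet_alpha = c(
                                      acinar = 1, lepidic = 1,
                                      micropapillary = 1, papillary = 1, solid = 1
                                    ),
                                    truth = NULL, n_genes = 10000,
                                    n_planted_per_subtype = 500,
                                    effect_size = 1.5, noise_sd = 1, seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (any(dirichlet_alpha <= 0)) stop("Dirichlet alphas must be > 0", call. = FALSE)
  if (is.null(names(dirichlet_alpha))) stop("dirichlet_alpha must be named", call. = FALSE)
  subtypes <- names(dirichlet_alpha)

  if (!is.null(truth)) {
    planted <- truth$genes
    n_genes <- truth$params$n_genes
    effect_size <- truth$params$effect_size
    noise_sd <- truth$params$noise_sd
    if (!all(planted$subtype %in% subtypes)) {
      stop("truth subtypes do not match dirichlet_alpha names", call. = FALSE)
    }
  }

  withr::with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    if (is.null(truth)) {
      planted <- plant_roles(genes, subtypes, n_planted_per_subtype, effect_size)
    }
    samples <- sprintf("m%03d", seq_len(n_samples))
    frac <- rdirichlet(n_samples, dirichlet_alpha) # n_samples x n_subtypes

    # subtype mean profiles: zero except planted genes at +/- effect
    mu <- matrix(0, nrow = n_genes, ncol = length(subtypes), dimnames = list(genes, subtypes))
    mu[cbind(match(planted$gene_id, genes), match(planted$subtype, subtypes))] <-
      planted$direction * effect_size * noise_sd

    expr <- mu %*% t(frac) + matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), nrow = n_genes)
    dimnames(expr) <- list(genes, samples)
  })

  fractions <- tibble::as_tibble(as.data.frame(frac))
  names(fractions) <- subtypes
  fractions <- dplyr::bind_cols(tibble::tibble(sample_id = samples), fractions)

  list(
    expression = expr,
    truth = list(
      genes = planted,
      fractions = fractions,
      params = list(
        n_samples = n_samples, dirichlet_alpha = dirichlet_alpha,
        n_genes = n_genes, effect_size = effect_size,
        noise_sd = noise_sd, seed = seed
      )
    )
  )
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Simulate survival from latent lepidic fractions
#'
#' Exponential event times with rate
#' `baseline_rate * exp(-log_hr * lepidic_fraction)`, so a higher lepidic
#' fraction lowers the hazard (the protective association the L-score is
#' built to capture). Censoring is independent: each sample is censored
#' with probability `censor_rate`, at a time drawn uniformly on
#' `(0, event_time)`.
#'
#' @param truth Truth from [generate_admixed_cohort()] (needs
#'   `fractions`) or any tibble with `sample_id` and `lepidic` columns
#'   passed via `fractions`.
#' @param baseline_rate Baseline exponential event rate per month.
#'   Default 0.02 (median survival near 3 years at fraction 0).
#' @param log_hr Log hazard ratio per unit lepidic fraction (positive =
#'   protective). Default `log(2)`.
#' @param censor_rate Probability a sample is censored. Default 0.2.
#' @param seed Integer seed.
#' @return Tibble: `sample_id`, `time` (months), `event` (0/1),
#'   `lepidic_fraction`.
#' @export
generate_survival <- function(truth, baseline_rate = 0.02, log_hr = log(2),
                              censor_rate = 0.2, seed = 1L) {
  fr <- truth$fractions
  if (is.null(fr) || !"lepidic" %in% names(fr)) {
    stop("truth must carry fractions with a lepidic column", call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]", call. = FALSE)
  n <- nrow(fr)
  withr::with_seed(seed, {
    rate <- baseline_rate * exp(-log_hr * fr$lepidic)
    t_event <- stats::rexp(n, rate = rate)
    censored <- stats::runif(n) < censor_rate
    time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  })
  tibble::tibble(
    sample_id = fr$sample_id,
    time = pmax(time, .Machine$double.eps),
    event = as.integer(!censored),
    lepidic_fraction = fr$lepidic
  )
}

#' Simulate outcome tables aligned to a synthetic cohort
#'
#' Three outcome structures, all driven by the latent lepidic fraction:
#' * `binary_features` — per-feature Bernoulli alteration status whose
#'   logit is linear in `1 - lepidic_fraction` (alterations enrich in
#'   low-lepidic tumors); `params`: `n_features`, `intercept`, `slope`.
#' * `drug_sensitivity` — continuous sensitivity (e.g. `-ln(IC50 + 1)`)
#'   linear in the fraction plus Gaussian noise; `params`: `intercept`,
#'   `slope`, `noise_sd`.
#' * `response` — binary responder labels with logit linear in the
#'   fraction; `params`: `intercept`, `slope`.
#'
#' @param truth Truth carrying `fractions` with a `lepidic` column.
#' @param kind One of `"binary_features"`, `"drug_sensitivity"`,
#'   `"response"`.
#' @param params Named list of generator parameters (see above); missing
#'   entries fall back to defaults (`intercept` 0 or -1, `slope` 1,
#'   `noise_sd` 1, `n_features` 100).
#' @param seed Integer seed.
#' @return `binary_features`: 0/1 matrix features x samples. Otherwise a
#'   tibble `sample_id` plus `sensitivity` or `response`.
#' @export
generate_outcomes <- function(truth,
                              kind = c("binary_features", "drug_sensitivity", "response"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  fr <- truth$fractions
  if (is.null(fr) || !"lepidic" %in% names(fr)) {
    stop("truth must carry fractions with a lepidic column", call. = FALSE)
  }
  n <- nrow(fr)
  p <- function(name, default) params[[name]] %||% default

  withr::with_seed(seed, switch(kind,
    binary_features = {
      nf <- p("n_features", 100)
      eta <- p("intercept", -1) + p("slope", 1) * (1 - fr$lepidic)
      prob <- stats::plogis(eta)
      m <- matrix(stats::rbinom(nf * n, 1L, rep(prob, each = nf)),
        nrow = nf,
        dimnames = list(sprintf("f%04d", seq_len(nf)), fr$sample_id)
      )
      m
    },
    drug_sensitivity = tibble::tibble(
      sample_id = fr$sample_id,
      sensitivity = p("intercept", 0) + p("slope", 1) * fr$lepidic +
        stats::rnorm(n, 0, p("noise_sd", 1))
    ),
    response = tibble::tibble(
      sample_id = fr$sample_id,
      response = stats::rbinom(n, 1L, stats::plogis(p("intercept", 0) + p("slope", 1) * fr$lepidic))
    )
  ))
}

#' Logistic slope giving a target AUC for a standard-normal score
#'
#' For scores `x ~ N(0, 1)` and labels drawn with
#' `P(y = 1 | x) = plogis(intercept + slope * x)`, finds by numerical
#' integration and root-finding the slope whose population AUC (the
#' probability a positive outscores a negative) equals `target_auc`.
#' Useful for building response simulations with a known discrimination
#' level.
#'
#' @param target_auc Target AUC in (0.5, 0.995].
#' @param intercept Logistic intercept (controls prevalence). Default 0.
#' @return The slope (positive scalar).
#' @export
logistic_slope_for_auc <- function(target_auc, intercept = 0) {
  stopifnot(target_auc > 0.5, target_auc <= 0.995)
  pop_auc <- function(b) {
    # class-conditional densities f1 ~ phi(x) p(x), f0 ~ phi(x)(1 - p(x)) on a grid
    x <- seq(-8, 8, length.out = 4001)
    px <- stats::plogis(intercept + b * x)
    phi <- stats::dnorm(x)
    f1 <- phi * px
    f0 <- phi * (1 - px)
    f1 <- f1 / sum(f1)
    f0 <- f0 / sum(f0)
    # P(X1 > X0) + 0.5 P(X1 = X0) over the grid
    sum(f1 * (cumsum(f0) - 0.5 * f0))
  }
  stats::uniroot(function(b) pop_auc(b) - target_auc, c(1e-6, 50))$root
}
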