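# histosig

Early-stage lung adenocarcinoma grows in five histologic patterns —
lepidic, acinar, papillary, micropapillary and solid — and most tumors mix
them. Lepidic growth is low-grade and carries a good prognosis; solid
growth is high-grade. Pathologists quantify the mixture on slides;
`histosig` quantifies it from bulk gene expression instead. It is aimed at
computational biologists who have a gene × sample expression table (log
microarray intensity or log TPM) and want per-sample **L-scores** and
**S-scores** — continuous measures of the lepidic and solid components —
plus the downstream prognostic, genomic, drug-sensitivity and
immunotherapy-response analyses those scores feed.

## The method

**Signatures.** From a cohort with pure-histology labels, each subtype is
contrasted against all other samples with a two-sample t-test (Student by
default), giving per-gene vectors {t} and {p}. These become a pair of
weight vectors in [0, 1]:

    w+_k = min(-ln p_k, 10) / 10   if t_k > 0, else 0
    w-_k = min(-ln p_k, 10) / 10   if t_k < 0, else 0

so up-regulated genes load `w+`, down-regulated genes load `w-`, and
significance saturates at p ≈ 4.5e-5 (the trim cap of 10).

**Scoring.** For one sample, genes are sorted by decreasing expression
into e = (e1, …, en) and a foreground running curve is compared with a
background curve:

    f(i) = Σ_{k≤i} |e_k w_k| / Σ_k |e_k w_k|
    b(i) = Σ_{k≤i} |e_k (1-w_k)| / Σ_k |e_k (1-w_k)|

The raw enrichment score is the signed value of f − b at its maximum
absolute deviation (the GSEA running-sum convention). It is z-normalized
against a null distribution from random permutations of the
gene-to-weight assignment, giving S⁺ from `w+` and S⁻ from `w-`, and the
final score is **S = S⁺ − S⁻**. The same engine scores any externally
supplied weight profile, e.g. immune-cell marker profiles for
infiltration estimates.

**Downstream.** Median or zero splits with log-rank tests, univariate and
multivariate Cox regression (hazard ratios with Wald CIs), Wilcoxon
rank-sum association of scores with binary mutation/amplification/deletion
features (tested when altered in ≥ 20 samples, flagged at p < 0.01),
Spearman correlation with drug sensitivity (−ln(IC50 + 1)), and ROC/AUC
for binary therapy response.

A synthetic-cohort generator (pure-subtype cohorts with planted
differential genes; Dirichlet-admixed cohorts with latent fractions;
survival, feature, drug and response outcomes driven by the latent
lepidic fraction) makes the whole pipeline testable without any download.

## Worked example

```r
library(histosig)
library(dplyr)

co <- generate_pure_cohort(n_genes = 2000, n_planted_per_subtype = 100, seed = 7)
dp <- differential_expression(co$expression, co$annotation, "lepidic")
head(arrange(dp, p), 3)
#>   gene_id     t        p        fdr target_subtype
#> 1 g00251  -7.75 6.90e-10 0.00000138 lepidic
#> 2 g00413   6.71 2.52e- 8 0.0000252  lepidic
#> 3 g01859   6.41 6.93e- 8 0.0000462  lepidic

sig <- build_weighted_signature(dp)            # w+ / w- in [0, 1]
ad  <- generate_admixed_cohort(30, truth = co$truth, seed = 8)
sc  <- score_cohort(ad$expression, sig, n_perm = 500, base_seed = 9)
sc[1:3, c("sample_id", "s_plus", "s_minus", "score")]
#>   sample_id s_plus s_minus  score
#> 1 m001       0.536  -0.803  1.34
#> 2 m002       0.777   1.65  -0.870
#> 3 m003       1.57   -2.13   3.70

rank_correlation(sc$score, ad$truth$fractions$lepidic)
#>     rho           p     n
#> 1 0.900 0.000000261    30

sv <- generate_survival(ad$truth, log_hr = 3, seed = 10)
logrank_test(dichotomize(sc$score), sv)
#>   statistic      p     n n_events
#> 1      4.80 0.0285    30       23
```

The first tibble is the lepidic-vs-rest differential profile (planted
genes surface with |t| ≈ 7). Each scored sample gets a normalized
enrichment pair and `score = s_plus - s_minus`; here the L-score recovers
the latent lepidic fraction of the admixed cohort at Spearman ρ = 0.90,
and a median split of the L-score separates survival (log-rank p = 0.029)
under a protective lepidic effect.

`run_build()` and `run_report()` drive the same steps from a YAML config
and write signatures, score tables, association TSVs and a run manifest.

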