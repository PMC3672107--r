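# mlgassoc

Multilocus genotype (MLG) association analysis for candidate-region
case-control SNP studies, with the surrounding pipeline: variant QC,
EM-based linkage-disequilibrium estimation, solid-spine haplotype-block
detection, covariate-adjusted logistic association with a global
deviance likelihood-ratio test, and the expression-side statistics such
studies pair with the genetics (ΔΔCt quantification, covariate-adjusted
gene–gene regression, exact small-sample nonparametric tests). A
synthetic-data module generates complete studies with known ground
truth so every stage is testable end to end.

## Who this is for

Complex-disease genetics groups fine-mapping a candidate region (the
motivating setting is late-onset Alzheimer's disease) where single-SNP
and haplotype tests are null but the *joint* genotype configuration of
a haplotype block may still carry signal. The MLG approach categorises
each subject by the combination of minor-allele counts across the
block's SNPs — one digit 0/1/2 per SNP, e.g. `MLG11010111` for an 8-SNP
block — and needs no phase estimation.

## The model

Within a block, with reference category the most common MLG, diagnosis
is modelled as

    logit P(case) = β₀ + Σₖ γₖ·1[MLG = k] + β'·(age, sex, APOE ε4 dosage, series)

`exp(γₖ)` is the odds ratio of MLG *k* versus the reference (Wald 95%
CI). MLGs with fewer than 10 carriers are pooled into `MLG-rare`;
categories with a zero cell or < 10 carriers stay in the model but
their estimates are masked (`NA_zero_cell`, `NA_small`). The global
test is the deviance LRT of this model against the covariates-only
model, χ² with df = number of MLG indicators — the primary inference,
requiring no per-MLG multiplicity correction.

Upstream, QC keeps variants with MAF > 0.01, call rate > 0.90 and
exact Hardy-Weinberg p > 0.0001 in controls; D′ comes from two-locus EM
on unphased dosages; blocks follow the solid-spine-of-LD rule (flanking
SNPs in strong D′ with each other and all intermediates, default
threshold 0.8).

## Worked example

Simulate a two-series case-control study (1500 + 1500 subjects) from
the default 8-SNP haplotype pool with a planted log-odds ratio of 0.5
on `MLG22000220`, then run QC and the MLG association:

```r
library(mlgassoc)

pool <- default_haplotype_pool()
cfg <- simulation_config(
  n_cases = 1500, n_controls = 1500, block = 1:8,
  mlg_log_odds = c(MLG22000220 = 0.5),
  covariate_effects = list(age = 0.02, sexmale = 0.1, apoe4 = 1.0),
  series_labels = c("JS", "RS"), series_offsets = c(0, 0.1),
  seed = 42)
study <- simulate_study(pool, cfg, missing_rate = 0.01)

qc  <- apply_qc(study$genotypes)
a   <- group_rare(assign_mlgs(qc$genotypes, 1:8), 10)
res <- mlg_association(a, study$subjects)
print(res)
```

```
MLG association: n = 2777, reference = MLG11010111
           mlg n_control n_case  p_wald odds_ratio ci_low_95 ci_high_95   status
1  MLG00002000         6      4 7.9e-01       0.84      0.23       3.06       ok
...
18 MLG22000220       141    243 1.2e-06       1.92      1.47       2.49       ok
19 MLG22010220        47     51 6.6e-01       1.10      0.71       1.72       ok
20    MLG-rare         6      3      NA         NA        NA         NA NA_small
global deviance LRT: chi2 = 50.138, df = 20, p = 0.0002116
```

2777 of the 3000 subjects have complete block genotypes; the planted
category `MLG22000220` is recovered with OR 1.92 (truth e^0.5 ≈ 1.65,
inside the CI), the other categories sit near OR 1, the 9-subject rare
pool is masked, and the global 20-df LRT is clearly significant.

The exact small-sample test used for 4-vs-4 replicate assays:

```r
mw <- mann_whitney_exact(c(536.2, 521.4, 530.9, 524.0),
                         c(447.7, 432.1, 444.8, 439.4))
#> U = 16, exact two-sided p = 0.0286  (reported as 0.03)
```

A shell pipeline over the same functions is available via
`inst/cli/mlgassoc` (subcommands `simulate`, `qc`, `ld-blocks`,
`mlg-assoc`, `snp-assoc`, `expr-assoc`, `ddct`, `group-test`); every
stage writes TSV/JSON outputs plus its resolved config and a run log.

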