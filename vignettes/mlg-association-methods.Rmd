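---
title: "Multilocus genotype association: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus genotype association: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlgassoc)
```

## The scientific problem

Candidate-region case-control studies of late-onset Alzheimer's disease
(LOAD) and similar complex diseases often find no significant single-SNP
or haplotype association and yet show a signal when the genotypes of a
haplotype block are considered jointly. The multilocus genotype (MLG)
approach tests exactly that: within a block of SNPs in strong linkage
disequilibrium, each subject's combination of minor-allele counts (one
digit 0/1/2 per SNP, e.g. `MLG11010111` for an 8-SNP block) defines a
category, and disease risk is compared across categories. Unlike
haplotype methods, no phase estimation is needed — the MLG is directly
observable from unphased genotypes.

`mlgassoc` implements the full chain of that analysis as a reusable,
tested pipeline: variant QC, LD estimation and block detection, MLG
construction, covariate-adjusted association with a global test, plus
the expression-side statistics such studies typically pair with the
genetics (relative qPCR quantification, adjusted gene–gene regression,
exact small-sample group tests).

## The association model

Within a block, let $m_i$ be subject $i$'s MLG. The most common MLG is
the reference; every other MLG $k$ (including the pooled rare category)
contributes an indicator $x_{ik} = \mathbb{1}[m_i = k]$. Diagnosis is
modelled by logistic regression

$$\operatorname{logit} P(\text{case}_i) \;=\; \beta_0
  + \sum_k \gamma_k x_{ik}
  + \beta^\top z_i,$$

with covariates $z_i$ = age at diagnosis/evaluation/death, sex, APOE
$\varepsilon4$ dosage (0/1/2, entered linearly) and series (dummy-coded).
$e^{\gamma_k}$ is the odds ratio of MLG $k$ versus the reference; Wald
95% CIs use $\pm 1.959964\,\mathrm{SE}$ on the log-odds scale. The
*global* test compares this model against the covariates-only model by
the deviance likelihood ratio: $\Lambda = D_\text{reduced} -
D_\text{full}$ referred to $\chi^2_{df}$ with $df$ = number of MLG
indicators. The global test is the primary inference — it does not
require multiplicity correction across the individual MLGs.

Sparse categories are handled by reporting rules rather than penalised
fits: an MLG with zero subjects in either diagnosis group, or fewer
than 10 carriers in total, is kept in the model (it still contributes a
degree of freedom to the global test) but its estimate is masked with a
status code (`NA_zero_cell`, `NA_small`). Separated terms — fitted
probabilities within $10^{-8}$ of 0/1 on the carrier set, coefficients
drifting to $\pm\infty$ while the likelihood plateaus — are flagged
`not_converged` individually; the fit is only considered globally
unstable when non-convergence is not explained by separation.

### Fitting

`logistic_irls()` maximises the binomial likelihood by iteratively
reweighted least squares (QR-based weighted solves, convergence when the
largest coefficient change drops below $10^{-8}$, cap 50 iterations).
The covariance is the inverse observed information. Tests verify the
log-likelihood against a derivative-free optimizer and against `glm()`
to $10^{-6}$; rank-deficient designs are rejected naming the collinear
columns rather than silently dropping them.

## Upstream: QC, LD, blocks

**Variant QC** keeps variants with MAF > 0.01, call rate > 0.90 and
exact Hardy-Weinberg p > 0.0001 in controls — all strict inequalities,
matching the usual "greater than" reporting convention. The HWE test is
the conditional exact test (enumeration of all heterozygote counts
compatible with the observed allele counts; two-sided p sums all
configurations no more probable than the observed one). The minor
allele is defined in the full sample by default (stable labels across
case/control splits), with a controls-only option; exact 50/50 ties
break to the lexicographically smaller allele symbol.

**LD** between two loci is estimated from unphased dosages by the
standard two-locus EM: only double heterozygotes are phase-ambiguous,
and their expected split follows the current haplotype-frequency
estimates. Iteration starts at linkage equilibrium and stops at a
$10^{-8}$ frequency change (cap 1000; non-convergence is flagged but
the estimate returned). From the ML frequencies, $D = p_{AB} - p_A
p_B$, $D' = |D|/D_\max$, $r^2 = D^2/(p_A p_a p_B p_b)$. Point
estimates of $D'$ are used directly — no confidence-interval
classification of "strong LD".

**Blocks** follow the solid-spine-of-LD rule: a run of map-ordered SNPs
is a block when its two flanking SNPs have $D'$ at or above the
threshold (default 0.8, the conventional strong-LD cut) with each other
and with every intermediate SNP. Blocks are grown greedily left to
right, taking the longest valid run from each start, so the output is
non-overlapping; ties between equally maximal overlapping candidates
resolve in favour of the leftmost start. Undefined $D'$ (monomorphic
pairs) counts as below threshold. A caveat worth knowing: for greedy
scans, mirror symmetry under reversing SNP order is guaranteed only
when candidate blocks do not overlap — with well-separated blocks (the
regime the method is meant for) the output is reversal-stable, and the
test suite checks exactly that regime.

**Rare MLGs** with fewer than 10 carriers in the analysed dataset are
pooled into `MLG-rare`. The threshold applies to the dataset being
fitted; to reproduce a pooled-cohort grouping, build the assignment on
the combined data (this mirrors how published tables typically apply
the "<10 in the combined cohorts" rule) — both choices are available by
construction.

## Expression-side statistics

**ΔΔCt.** Replicate wells are averaged per (sample, gene); $\Delta Ct =
Ct_\text{target} - Ct_\text{control}$; $\Delta\Delta Ct$ subtracts the
calibrator sample's $\Delta Ct$ gene-wise; relative expression is
$2^{-\Delta\Delta Ct}$ (amplification efficiency 2). Several control
genes are combined by averaging their Cts, which equals the geometric
mean of their expression levels on the Ct (log2) scale.

**Adjusted regression.** Gene–gene association in bulk brain tissue is
confounded by cell-type composition and technical batch, so the
regression of one gene's level on another adjusts for APOE ε4 dosage,
age at death, sex, PCR plate (dummy-coded), RIN, a centered squared RIN
term, diagnosis, and the expression of five cell-type marker genes
(neuronal ENO2, astrocytic GFAP, microglial CD68, oligodendrocytic
OLIG2, endothelial CD34). The squared RIN term is centered at the mean
RIN *of the rows actually fitted* (computed per region/subset), which
keeps it nearly orthogonal to the linear term. Published effect sizes
from real ~400-brain datasets are not reproducible without those data;
the regression design is instead validated by simulation (planted
$\beta = 0.15$, $n = 400$: bias and CI coverage checked over 100
replicates).

**Exact group tests.** With $n = 4$ replicates per arm the normal
approximation to the Mann-Whitney U is invalid, so the test enumerates
the full permutation null (dynamic programming over doubled mid-ranks,
exactly equivalent to enumerating all $\binom{n_1+n_2}{n_1}$
assignments; ties take mid-ranks). The two-sided p is $2\min(\text{tail
probabilities})$ capped at 1 — for two fully separated groups of four,
$p = 2/70 \approx 0.0286$, printed as 0.03. Multi-group comparisons use
the tie-corrected Kruskal-Wallis H with a $\chi^2_{k-1}$ reference;
the analysis unit is experiment-level averages, matching how replicated
qPCR designs are usually summarised.

## The synthetic-data generator

Analyses are validated end to end on simulated studies whose ground
truth is known. Design choices:

* **Haplotype pools, not coalescent simulation.** Block LD is the only
  genotype structure the analyses consume, and a hand-specified pool
  gives exact, analytically known D′ and MLG frequencies
  (`pool_ld()` computes them). Each subject is two independent pool
  draws, so HWE holds exactly at every SNP; missingness is i.i.d.
* **Default pool:** 8 SNPs, 6 haplotypes whose common diplotypes echo
  the MLG multiplicity of real candidate-region blocks (a dominant
  heterozygous MLG near 25%, two homozygote MLGs near 12–14%, a tail of
  low-frequency MLGs).
* **Phenotype model:** case probability is
  $\operatorname{logit}^{-1}(\beta_0 + \gamma_{m_i} + \beta^\top z_i)$ —
  the same model the association stage fits, inverted. Covariates are
  age ~ Normal(74, 6) truncated at ≥ 60 years (a late-onset inclusion
  criterion), sex ~ Bernoulli(1/2), APOE ε4 dosage multinomial
  (0.60/0.35/0.05), series uniform with additive offsets; age enters
  centered at 74. Fixed case/control quotas are met by retrospective
  sampling (oversampling the pool up to 100×), which leaves odds ratios
  identified — only the intercept shifts.
* **Determinism:** every generator takes a seed; a fixed seed
  reproduces byte-identical studies on disk.

What the simulations do *not* emulate: population stratification,
relatedness, genotyping-error structure beyond random missingness,
recombination within blocks, and array-preprocessing artefacts on the
expression side. Passing tests therefore demonstrate the statistical
machinery is correct under the stated model, not robustness to those
real-data complications.

## Validation suite and problem sizes

The test suite ties each stage to an independent oracle and checks the
statistical properties the pipeline's inferences rely on, at sizes
chosen to keep the full suite in the minutes range:

* exact HWE p equal to exhaustive enumeration for **every**
  configuration up to $n = 30$ (and, via a separate slot-level
  enumeration, for spot configurations);
* two-locus EM log-likelihood within $10^{-6}$ of a dense grid search
  over the free haplotype frequency, on 20-subject fixtures;
* IRLS log-likelihood within $10^{-6}$ of a derivative-free optimizer
  on 60–80-subject fixtures;
* exact Mann-Whitney p equal to `combn()` enumeration across tied and
  untied configurations;
* global LRT type-I error within [0.03, 0.07] over 1000 null
  simulations (500 subjects, ~6 MLG terms, covariate effects present);
* planted MLG log-OR 1.0 and covariate effects recovered with |bias|
  < 0.05 and 90–99% CI coverage over 100 replicates at $n = 5000$;
  likewise a planted expression $\beta = 0.15$ at $n = 400$;
* solid-spine detection recovering ≥ 75% of a planted high-LD
  (pool D′ ≥ 0.9) 8-SNP block at $n = 2000$;
* D′ estimates converging to pool truth (per-pair median error < 0.05
  over replicates at $n = 2000$ — single-draw D′ error for near-zero-LD
  pairs sits right at that scale, which is why the median is used).

## Known limitations

* Separation is reported, not corrected: no Firth/penalised fallback.
  The masking rules (zero cell, < 10 carriers) are the intended
  treatment of sparse MLGs.
* The greedy spine scan can in principle differ from a right-to-left
  scan when maximal candidate blocks overlap.
* Minor-allele labels for monomorphic variants cannot be resolved from
  PED data alone (the second allele is unobserved); such variants are
  flagged and fail the MAF filter anyway.
* Haplotype score tests, Gabriel-interval blocks, imputation, VCF/BED
  input, and population-structure QC are out of scope.
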