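# Synthetic-study generators with known ground truth: haplotype-pool
# genotypes with block LD, retrospective case-control phenotypes driven
# by planted MLG and covariate effects, expression tables, qPCR Ct
# tables and small replicate assay groups.

#' Haplotype pool
#'
#' A pool of binary haplotypes with frequencies, defining the joint
#' allele distribution genotypes are drawn from (two independent
#' haplotype draws per subject, i.e. Hardy-Weinberg at every locus).
#' Allele 1 is the intended minor allele at each SNP.
#'
#' @param haplotypes 0/1 matrix, one row per haplotype.
#' @param freqs haplotype frequencies, summing to 1.
#' @param snp_ids,chromosome,positions optional variant metadata;
#'   positions default to 1000 * (1..m).
#' @return object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(haplotypes, freqs, snp_ids = NULL,
                           chromosome = "10", positions = NULL) {
  h <- as.matrix(haplotypes)
  if (!all(h %in% c(0, 1))) stop("haplotypes must be 0/1")
  if (nrow(h) < 2L) stop("need at least 2 distinct haplotypes")
  if (length(freqs) != nrow(h)) stop("one frequency per haplotype required")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("haplotype frequencies must be non-negative and sum to 1")
  m <- ncol(h)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%02d", seq_len(m))
  if (is.null(positions)) positions <- 1000L * seq_len(m)
  structure(list(haplotypes = h, freqs = as.numeric(freqs),
                 snp_ids = snp_ids, chromosome = chromosome,
                 positions = as.integer(positions)),
            class = "haplotype_pool")
}

#' Default 8-SNP haplotype pool
#'
#' Six haplotypes over 8 SNPs whose commonest diplotypes echo the MLG
#' multiplicity seen in real candidate-region blocks: the two major
#' haplotypes produce a dominant heterozygous MLG (11010111-style) plus
#' the two corresponding homozygote MLGs, and four minor haplotypes add
#' a realistic tail of mid- and low-frequency MLGs.
#' @return haplotype_pool
#' @export
default_haplotype_pool <- function() {
  h <- rbind(
    c(0, 0, 0, 1, 0, 0, 0, 1),
    c(1, 1, 0, 0, 0, 1, 1, 0),
    c(0, 0, 1, 0, 0, 0, 0, 0),
    c(0, 0, 0, 0, 1, 0, 0, 0),
    c(1, 1, 0, 1, 0, 1, 1, 0),
    c(0, 0, 0, 1, 1, 0, 0, 1))
  haplotype_pool(h, c(0.35, 0.37, 0.12, 0.06, 0.05, 0.05))
}

#' Theoretical pairwise D'/r2 of a haplotype pool
#'
#' Computes two-locus haplotype frequencies by marginalizing the pool and
#' evaluates the same D'/r2 formulas the estimator uses, giving the
#' ground-truth LD the estimated matrices should converge to.
#' @param pool haplotype_pool
#' @return list of matrices `dprime`, `r2`
#' @export
pool_ld <- function(pool) {
  h <- pool$haplotypes; f <- pool$freqs; m <- ncol(h)
  dp <- matrix(NA_real_, m, m, dimnames = list(pool$snp_ids, pool$snp_ids))
  r2 <- dp
  diag(dp) <- 1; diag(r2) <- 1
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    pAB <- sum(f[h[, i] == 1 & h[, j] == 1])
    pAb <- sum(f[h[, i] == 1 & h[, j] == 0])
    paB <- sum(f[h[, i] == 0 & h[, j] == 1])
    ld <- dprime_r2(list(p_AB = pAB, p_Ab = pAb, p_aB = paB,
                         p_ab = 1 - pAB - pAb - paB))
    dp[i, j] <- dp[j, i] <- ld$dprime
    r2[i, j] <- r2[j, i] <- ld$r2
  }
  list(dprime = dp, r2 = r2)
}

#' Simulate unphased genotypes from a haplotype pool
#'
#' Each subject is two independent haplotype draws; dosage counts allele
#' 1 (the pool's intended minor allele). Genotypes are then masked
#' missing i.i.d. at `missing_rate`. Raw allele symbols are attached
#' (allele 1 = "G", allele 0 = "A") so the simulated study can be written
#' to PED/MAP and pushed through the full reading/recoding path.
#'
#' @param pool haplotype_pool
#' @param n number of subjects
#' @param missing_rate i.i.d. per-genotype missingness
#' @param seed optional RNG seed (set via [set.seed()] when given)
#' @return genotype_matrix (diagnosis unset)
#' @export
simulate_genotypes <- function(pool, n, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, missing_rate >= 0, missing_rate < 1)
  m <- ncol(pool$haplotypes)
  i1 <- sample.int(nrow(pool$haplotypes), n, replace = TRUE, prob = pool$freqs)
  i2 <- sample.int(nrow(pool$haplotypes), n, replace = TRUE, prob = pool$freqs)
  h1 <- pool$haplotypes[i1, , drop = FALSE]
  h2 <- pool$haplotypes[i2, , drop = FALSE]
  dosage <- h1 + h2
  if (missing_rate > 0)
    dosage[matrix(stats::runif(n * m) < missing_rate, n, m)] <- NA_integer_
  sym <- function(hh) matrix(c("A", "G")[hh + 1L], n, m)
  a1 <- sym(h1); a2 <- sym(h2)
  a1[is.na(dosage)] <- NA_character_; a2[is.na(dosage)] <- NA_character_
  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    diagnosis = factor(rep(NA_character_, n), levels = c("control", "case")),
    sex = factor(rep(NA_character_, n), levels = c("male", "female")),
    stringsAsFactors = FALSE)
  variants <- data.frame(snp_id = pool$snp_ids, chromosome = pool$chromosome,
                         position = pool$positions,
                         allele_a = "A", allele_b = "G", minor_allele = "G",
                         maf = colMeans(dosage, na.rm = TRUE) / 2,
                         call_rate = colMeans(!is.na(dosage)),
                         monomorphic = apply(dosage, 2, function(d)
                           length(unique(d[!is.na(d)])) < 2L),
                         stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, subjects, alleles = list(a1 = a1, a2 = a2))
}

#' Simulation configuration for a case-control study
#'
#' Ground-truth parameters of the phenotype model: the probability of
#' being a case is logistic(baseline + MLG effect + covariate effects +
#' series offset). Covariates are drawn as age ~ Normal(74, 6) truncated
#' at >= 60 years (a late-onset inclusion criterion), sex ~ Bernoulli(1/2),
#' APOE e4 dosage ~ multinomial on 0/1/2, series ~ uniform categorical.
#' Age enters the linear predictor centered at 74 so the baseline stays
#' interpretable.
#'
#' @param n_cases,n_controls target group sizes (NULL to keep every
#'   simulated subject with their drawn diagnosis).
#' @param block variant indices the MLG effects refer to.
#' @param mlg_log_odds named numeric, MLG label -> log-odds shift.
#' @param covariate_effects list with age, sexmale, apoe4 log-odds.
#' @param series_labels,series_offsets categorical series with additive
#'   log-odds offsets (first offset conventionally 0).
#' @param apoe4_probs multinomial probabilities for dosage 0/1/2.
#' @param baseline_log_odds intercept of the risk model.
#' @param seed RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = NULL, n_controls = NULL,
                              block = 1:8,
                              mlg_log_odds = c(),
                              covariate_effects = list(age = 0, sexmale = 0, apoe4 = 0),
                              series_labels = c("S1", "S2"),
                              series_offsets = c(0, 0),
                              apoe4_probs = c(0.60, 0.35, 0.05),
                              baseline_log_odds = 0,
                              seed = NULL) {
  stopifnot(length(series_labels) == length(series_offsets),
            length(apoe4_probs) == 3L)
  structure(list(n_cases = n_cases, n_controls = n_controls, block = block,
                 mlg_log_odds = mlg_log_odds,
                 covariate_effects = covariate_effects,
                 series_labels = series_labels,
                 series_offsets = series_offsets,
                 apoe4_probs = apoe4_probs,
                 baseline_log_odds = baseline_log_odds, seed = seed),
            class = "simulation_config")
}

rtrunc_age <- function(n, mean = 74, sd = 6, lower = 60) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

#' Simulate diagnosis and covariates for simulated genotypes
#'
#' Draws covariates for every subject of `g`, computes each subject's MLG
#' over `config$block`, assigns case/control by the logistic risk model,
#' and (when `n_cases`/`n_controls` are set) retrospectively samples the
#' requested numbers of cases and controls. Retrospective sampling leaves
#' odds ratios identified (only the intercept shifts), matching how
#' case-control series are actually ascertained.
#'
#' @param g genotype_matrix from [simulate_genotypes()] (pass an
#'   oversampled one when fixed group sizes are requested; see
#'   [simulate_study()]).
#' @param config simulation_config.
#' @return list of class `simulated_study`: `genotypes` (subset of g),
#'   `subjects` (covariate table incl. diagnosis), `truth` (the config).
#' @export
simulate_case_control <- function(g, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- n_subjects(g)
  age <- rtrunc_age(n)
  sex <- factor(ifelse(stats::runif(n) < 0.5, "male", "female"),
                levels = c("male", "female"))
  apoe4 <- sample(0:2, n, replace = TRUE, prob = config$apoe4_probs)
  series <- sample(config$series_labels, n, replace = TRUE)
  d <- g$dosage[, config$block, drop = FALSE]
  complete <- rowSums(is.na(d)) == 0L
  lab <- rep(NA_character_, n)
  if (any(complete))
    lab[complete] <- paste0("MLG", apply(d[complete, , drop = FALSE], 1,
                                         paste, collapse = ""))
  mlg_eff <- rep(0, n)
  hit <- !is.na(lab) & lab %in% names(config$mlg_log_odds)
  mlg_eff[hit] <- config$mlg_log_odds[lab[hit]]
  ce <- config$covariate_effects
  lp <- config$baseline_log_odds + mlg_eff +
    ce$age * (age - 74) + ce$sexmale * (sex == "male") + ce$apoe4 * apoe4 +
    config$series_offsets[match(series, config$series_labels)]
  case <- stats::runif(n) < stats::plogis(lp)
  keep <- seq_len(n)
  if (!is.null(config$n_cases) || !is.null(config$n_controls)) {
    ic <- which(case); iu <- which(!case)
    if (length(ic) < config$n_cases || length(iu) < config$n_controls)
      stop(sprintf(
        "simulated pool yields %d cases / %d controls; %d / %d requested (oversample the pool)",
        length(ic), length(iu), config$n_cases, config$n_controls))
    keep <- sort(c(ic[seq_len(config$n_cases)], iu[seq_len(config$n_controls)]))
  }
  subjects <- data.frame(
    subject_id = g$subjects$subject_id[keep],
    diagnosis = factor(ifelse(case[keep], "case", "control"),
                       levels = c("control", "case")),
    age = age[keep], sex = sex[keep], apoe4_dosage = apoe4[keep],
    series = series[keep], stringsAsFactors = FALSE)
  gk <- genotype_matrix(
    g$dosage[keep, , drop = FALSE], g$variants,
    transform(g$subjects[keep, , drop = FALSE],
              diagnosis = subjects$diagnosis, sex = subjects$sex),
    alleles = if (!is.null(g$alleles))
      lapply(g$alleles, function(a) a[keep, , drop = FALSE]))
  structure(list(genotypes = gk, subjects = subjects, truth = config),
            class = "simulated_study")
}

#' One-call study simulation with oversampling
#'
#' Draws genotype batches from the pool and applies the risk model until
#' the requested numbers of cases and controls are reached (error after a
#' 100x oversampling budget).
#'
#' @param pool haplotype_pool
#' @param config simulation_config with n_cases and n_controls set.
#' @param missing_rate per-genotype missingness.
#' @return simulated_study
#' @export
simulate_study <- function(pool, config, missing_rate = 0) {
  stopifnot(inherits(config, "simulation_config"),
            !is.null(config$n_cases), !is.null(config$n_controls))
  if (!is.null(config$seed)) set.seed(config$seed)
  target <- config$n_cases + config$n_controls
  n_draw <- 2L * target
  repeat {
    g <- simulate_genotypes(pool, n_draw, missing_rate = missing_rate)
    cfg <- config; cfg$seed <- NULL    # RNG already seeded; keep stream
    study <- tryCatch(simulate_case_control(g, cfg), error = function(e) e)
    if (!inherits(study, "error")) { study$truth <- config; return(study) }
    if (n_draw >= 100L * target)
      stop("requested n_cases/n_controls unattainable within 100x oversampling")
    n_draw <- min(2L * n_draw, 100L * target)
  }
}

#' Write a simulated study to disk
#'
#' PED/MAP genotypes, covariate TSV and a ground-truth JSON sidecar, the
#' same formats the pipeline reads.
#' @param study simulated_study
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @export
write_simulated_study <- function(study, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- file.path(dir, paste0(prefix, ".ped"))
  map <- file.path(dir, paste0(prefix, ".map"))
  cov <- file.path(dir, paste0(prefix, "_covariates.tsv"))
  truth <- file.path(dir, paste0(prefix, "_truth.json"))
  write_ped_map(study$genotypes, ped, map)
  write_covariates(study$subjects, cov)
  tr <- unclass(study$truth)
  tr$mlg_log_odds <- as.list(tr$mlg_log_odds)
  jsonlite::write_json(tr, truth, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(ped = ped, map = map, covariates = cov, truth = truth))
}

#' Simulate an expression table with a planted gene-gene effect
#'
#' Outcome = true_beta * predictor + nuisance covariate effects +
#' Gaussian noise; predictor and marker covariates are standard normal,
#' plate is a 4-level factor with offsets, RIN ~ Normal(7.5, 1),
#' diagnosis ~ Bernoulli(1/2). The generating parameters are attached as
#' attribute `truth`.
#'
#' @param n rows
#' @param true_beta planted coefficient of `predictor`.
#' @param nuisance named list of covariate effect sizes; any of
#'   diagnosis, age, sexmale, apoe4, rin, rin2, plate (vector of 4
#'   offsets), markers (vector of 5 effects).
#' @param noise_sd residual SD (> 0).
#' @param seed RNG seed.
#' @return data.frame with outcome, predictor, covariates and five
#'   cell-type marker columns (marker_neuron, marker_astro,
#'   marker_microglia, marker_oligo, marker_endo).
#' @export
simulate_expression <- function(n, true_beta, nuisance = list(),
                                noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise_sd > 0)
  def <- list(diagnosis = 0, age = 0, sexmale = 0, apoe4 = 0,
              rin = 0, rin2 = 0, plate = rep(0, 4), markers = rep(0, 5))
  nu <- utils::modifyList(def, nuisance)
  predictor <- stats::rnorm(n)
  diagnosis <- stats::rbinom(n, 1, 0.5)
  age <- stats::rnorm(n, 80, 8)
  sexmale <- stats::rbinom(n, 1, 0.5)
  apoe4 <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.35, 0.05))
  plate <- factor(sample(paste0("P", 1:4), n, replace = TRUE))
  rin <- stats::rnorm(n, 7.5, 1)
  markers <- matrix(stats::rnorm(5 * n), n, 5,
                    dimnames = list(NULL, c("marker_neuron", "marker_astro",
                                            "marker_microglia", "marker_oligo",
                                            "marker_endo")))
  outcome <- true_beta * predictor + nu$diagnosis * diagnosis +
    nu$age * (age - 80) + nu$sexmale * sexmale + nu$apoe4 * apoe4 +
    nu$rin * (rin - 7.5) + nu$rin2 * (rin - 7.5)^2 +
    nu$plate[as.integer(plate)] + drop(markers %*% nu$markers) +
    stats::rnorm(n, 0, noise_sd)
  out <- data.frame(outcome = outcome, predictor = predictor,
                    diagnosis = diagnosis, age = age, sexmale = sexmale,
                    apoe4_dosage = apoe4, plate = plate, rin = rin,
                    markers, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(true_beta = true_beta, nuisance = nu,
                             noise_sd = noise_sd)
  out
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Target-gene Cts are base_ct - log2(fold change) + noise (amplification
#' efficiency 2: one cycle per doubling); control-gene Cts are flat at
#' their base. One sample per (treatment, experiment), `n_replicates`
#' wells each.
#'
#' @param treatments character vector of treatment-group labels; the
#'   first is the calibrator group.
#' @param fold_changes named list: target gene -> named numeric of fold
#'   changes per treatment (1 = no change).
#' @param control_gene control gene name (default "HPRT").
#' @param n_experiments independent experiments per treatment.
#' @param n_replicates wells per (sample, gene) (default quadruplicate).
#' @param noise_sd well-to-well Ct noise in cycles.
#' @param base_ct baseline cycle threshold.
#' @param seed RNG seed.
#' @return data.frame: sample_id, treatment_group, gene, replicate_index,
#'   ct; calibrator sample id in attribute `calibrator`.
#' @export
simulate_ct <- function(treatments, fold_changes, control_gene = "HPRT",
                        n_experiments = 1L, n_replicates = 4L,
                        noise_sd = 0.2, base_ct = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise_sd > 0, n_replicates >= 1L)
  genes <- names(fold_changes)
  rows <- list()
  for (tr in treatments) for (e in seq_len(n_experiments)) {
    sid <- sprintf("%s_exp%d", tr, e)
    for (gn in c(genes, control_gene)) {
      fc <- if (gn %in% genes) {
        v <- fold_changes[[gn]]
        if (!tr %in% names(v)) stop("fold change missing for ", gn, " in ", tr)
        v[[tr]]
      } else 1
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, treatment_group = tr, gene = gn,
        replicate_index = seq_len(n_replicates),
        ct = base_ct - log2(fc) + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "calibrator") <- sprintf("%s_exp1", treatments[1])
  out
}

#' Simulate small replicate assay groups
#'
#' Normal(mean, sd) measurements for each group, emulating e.g. 4-vs-4
#' ELISA designs.
#' @param n_per_group replicates per group.
#' @param means,sds named numeric vectors (same names).
#' @param seed RNG seed.
#' @return data.frame: group, value
#' @export
simulate_assay_groups <- function(n_per_group, means, sds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(means) == length(sds), all(sds > 0))
  groups <- names(means)
  if (is.null(groups)) groups <- paste0("g", seq_along(means))
  do.call(rbind, lapply(seq_along(means), function(i)
    data.frame(group = groups[i],
               value = stats::rnorm(n_per_group, means[i], sds[i]),
               stringsAsFactors = FALSE)))
}
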