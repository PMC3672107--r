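# Covariate-adjusted association models: per-MLG logistic regression with
# a global deviance LRT, and single-SNP additive logistic regression.

WALD_Z <- 1.959964  # two-sided 95% critical value

build_covariate_design <- function(subjects, adjust) {
  cols <- list("(Intercept)" = rep(1, nrow(subjects)))
  for (v in adjust) {
    switch(v,
      age = { cols$age <- subjects$age },
      sex = { cols$sexmale <- as.numeric(subjects$sex == "male") },
      apoe4_dosage = { cols$apoe4_dosage <- as.numeric(subjects$apoe4_dosage) },
      series = {
        s <- factor(subjects$series)
        if (nlevels(s) > 1L) {
          mm <- stats::model.matrix(~s)[, -1, drop = FALSE]
          colnames(mm) <- paste0("series", levels(s)[-1])
          for (k in seq_len(ncol(mm))) cols[[colnames(mm)[k]]] <- mm[, k]
        }
      },
      stop("unknown covariate: ", v))
  }
  do.call(cbind, cols)
}

term_summary <- function(fit, term) {
  est <- fit$coefficients[term]
  se <- sqrt(fit$vcov[term, term])
  z <- est / se
  data.frame(term = term, estimate = unname(est),
             odds_ratio = exp(unname(est)),
             ci_low_95 = exp(unname(est) - WALD_Z * se),
             ci_high_95 = exp(unname(est) + WALD_Z * se),
             p_wald = 2 * stats::pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted MLG case-control association
#'
#' Fits a logistic model of diagnosis on one 0/1 indicator per
#' non-reference MLG (each subject gets 1 for the MLG they carry, 0
#' otherwise; the most common MLG is the reference) plus the requested
#' covariates, and compares it with the covariates-only model by the
#' global deviance likelihood-ratio test ([global_lrt()]), whose degrees
#' of freedom equal the number of MLG indicators.
#'
#' Per-MLG Wald statistics give odds ratios with 95% confidence intervals
#' (log-odds scale, critical value 1.959964). Results are masked with a
#' status code instead of an estimate when a diagnosis group has zero
#' carriers of the MLG (`NA_zero_cell`), when fewer than `na_min_total`
#' subjects carry it (`NA_small`), or when the fit flagged separation /
#' non-convergence for that term (`not_converged`); the indicators still
#' enter the model and the global test. Subjects with missing covariates,
#' diagnosis, or block genotypes are dropped listwise.
#'
#' @param a mlg_assignment, typically after [group_rare()].
#' @param subjects covariate data.frame from [read_covariates()] (must
#'   cover the assigned subjects by subject_id).
#' @param adjust covariates to include; any of "age", "sex",
#'   "apoe4_dosage", "series".
#' @param na_min_total mask per-MLG estimates when carrier total is below
#'   this (default 10).
#' @param bonferroni add a `p_bonf` column with per-MLG Wald p-values
#'   Bonferroni-adjusted for the number of tested MLGs (default FALSE:
#'   the global LRT, not the per-MLG tests, is the primary inference).
#' @return object of class `association_result`: `terms` data.frame (mlg,
#'   counts, estimate, odds_ratio, ci_low_95, ci_high_95, p_wald, status),
#'   `global` (statistic, df, p_value), `reference`, `n_fitted`, `fit`,
#'   `fit_reduced`.
#' @export
mlg_association <- function(a, subjects,
                            adjust = c("age", "sex", "apoe4_dosage", "series"),
                            na_min_total = 10L, bonferroni = FALSE) {
  stopifnot(inherits(a, "mlg_assignment"))
  idx <- match(names(a$labels), subjects$subject_id)
  if (anyNA(idx))
    stop("covariates missing for subject(s): ",
         paste(utils::head(names(a$labels)[is.na(idx)], 3), collapse = ", "))
  sub <- subjects[idx, , drop = FALSE]
  lab <- unname(a$labels)
  need <- intersect(c("age", "sex", "apoe4_dosage", "series"), adjust)
  ok <- !is.na(lab) & !is.na(sub$diagnosis)
  for (v in need) ok <- ok & !is.na(sub[[v]])
  sub <- sub[ok, , drop = FALSE]; lab <- lab[ok]
  if (!a$reference %in% lab)
    stop("reference MLG ", a$reference, " absent among fitted subjects")
  mlgs <- sort(setdiff(unique(lab), a$reference))
  if ("MLG-rare" %in% mlgs) mlgs <- c(setdiff(mlgs, "MLG-rare"), "MLG-rare")
  Xcov <- build_covariate_design(sub, adjust)
  Xmlg <- vapply(mlgs, function(m) as.numeric(lab == m),
                 numeric(length(lab)))
  X <- cbind(Xcov, Xmlg)
  colnames(X) <- c(colnames(Xcov), mlgs)
  y <- as.numeric(sub$diagnosis == "case")
  fit_full <- logistic_irls(X, y)
  fit_red <- logistic_irls(Xcov, y)
  lrt <- global_lrt(fit_full, fit_red)

  # non-convergence caused solely by separated terms (coefficients
  # drifting to +-Inf while the likelihood plateaus) only masks those
  # terms; unexplained non-convergence masks everything
  unstable_all <- !fit_full$converged && !any(fit_full$separation)
  rows <- lapply(mlgs, function(m) {
    nc <- sum(lab == m & y == 0); na_ <- sum(lab == m & y == 1)
    st <- term_summary(fit_full, m)
    status <- "ok"
    if (nc == 0L || na_ == 0L) status <- "NA_zero_cell"
    else if (nc + na_ < na_min_total) status <- "NA_small"
    else if (fit_full$separation[m] || unstable_all) status <- "not_converged"
    if (status != "ok")
      st[, c("estimate", "odds_ratio", "ci_low_95", "ci_high_95", "p_wald")] <- NA_real_
    data.frame(mlg = m, n_control = nc, n_case = na_, st[-1],
               status = status, stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, rows)
  rownames(terms) <- NULL
  if (bonferroni)
    terms$p_bonf <- stats::p.adjust(terms$p_wald, method = "bonferroni")
  structure(list(terms = terms, global = lrt, reference = a$reference,
                 n_fitted = length(y), adjust = adjust,
                 fit = fit_full, fit_reduced = fit_red),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("MLG association: n = %d, reference = %s\n", x$n_fitted, x$reference))
  df <- x$terms
  df$odds_ratio <- round(df$odds_ratio, 2)
  df$ci_low_95 <- round(df$ci_low_95, 2); df$ci_high_95 <- round(df$ci_high_95, 2)
  df$p_wald <- signif(df$p_wald, 2)
  print(df[, c("mlg", "n_control", "n_case", "p_wald", "odds_ratio",
               "ci_low_95", "ci_high_95", "status")])
  cat(sprintf("global deviance LRT: chi2 = %.3f, df = %d, p = %.4g\n",
              x$global$statistic, x$global$df, x$global$p_value))
  invisible(x)
}

#' Single-SNP additive logistic association
#'
#' Per variant, minor-allele dosage (0/1/2) enters as one linear term in
#' a logistic model of diagnosis with the requested covariates; the
#' reported odds ratio is per copy of the minor allele. Subjects missing
#' that variant's genotype, diagnosis, or a covariate are dropped for
#' that variant only. Monomorphic variants get status "NA_monomorphic".
#'
#' @inheritParams mlg_association
#' @param g recoded (typically QC'd) genotype_matrix.
#' @return data.frame: snp_id, n, estimate, odds_ratio, ci_low_95,
#'   ci_high_95, p_wald, status.
#' @export
single_snp_association <- function(g, subjects,
                                   adjust = c("age", "sex", "apoe4_dosage", "series")) {
  if (is.null(g$dosage)) stop("genotypes must be minor-allele coded first")
  idx <- match(g$subjects$subject_id, subjects$subject_id)
  if (anyNA(idx))
    stop("covariates missing for subject(s): ",
         paste(utils::head(g$subjects$subject_id[is.na(idx)], 3), collapse = ", "))
  sub_all <- subjects[idx, , drop = FALSE]
  need <- intersect(c("age", "sex", "apoe4_dosage", "series"), adjust)
  rows <- lapply(seq_len(n_variants(g)), function(j) {
    d <- g$dosage[, j]
    ok <- !is.na(d) & !is.na(sub_all$diagnosis)
    for (v in need) ok <- ok & !is.na(sub_all[[v]])
    d <- d[ok]; sub <- sub_all[ok, , drop = FALSE]
    out <- data.frame(snp_id = g$variants$snp_id[j], n = sum(ok),
                      estimate = NA_real_, odds_ratio = NA_real_,
                      ci_low_95 = NA_real_, ci_high_95 = NA_real_,
                      p_wald = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    if (length(unique(d)) < 2L) { out$status <- "NA_monomorphic"; return(out) }
    X <- cbind(build_covariate_design(sub, adjust), dosage = as.numeric(d))
    fit <- logistic_irls(X, as.numeric(sub$diagnosis == "case"))
    st <- term_summary(fit, "dosage")
    out$estimate <- st$estimate; out$odds_ratio <- st$odds_ratio
    out$ci_low_95 <- st$ci_low_95; out$ci_high_95 <- st$ci_high_95
    out$p_wald <- st$p_wald
    if (fit$separation["dosage"] || !fit$converged) out$status <- "not_converged"
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write MLG association results as TSV
#'
#' Columns mirror the usual MLG report: MLG, control and case counts with
#' within-group frequencies, Wald p, OR and 95% CI, status, followed by a
#' one-row global summary file.
#' @param res association_result
#' @param a the mlg_assignment the model was fitted on (for frequencies)
#' @param path output TSV path; the global summary goes to
#'   `sub("\\.tsv$", "_global.tsv", path)`.
#' @export
write_mlg_results <- function(res, a, path) {
  freq <- mlg_frequency_table(a)
  tab <- merge(freq[, c("mlg", "n_control", "freq_control", "n_case", "freq_case")],
               res$terms[, c("mlg", "p_wald", "odds_ratio", "ci_low_95",
                             "ci_high_95", "status")],
               by = "mlg", all.x = TRUE)
  tab$status[tab$mlg == res$reference] <- "REF"
  tab <- tab[order(tab$mlg == "MLG-rare", tab$mlg), , drop = FALSE]  # rare last
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gpath <- sub("\\.tsv$", "_global.tsv", path)
  utils::write.table(
    data.frame(statistic = res$global$statistic, df = res$global$df,
               p_global = res$global$p_value, n = res$n_fitted,
               reference = res$reference),
    gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, gpath))
}
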