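# Expression-side statistics: delta-delta-Ct relative quantification,
# covariate-adjusted gene-gene regression, and exact small-sample
# nonparametric group tests.

#' Delta-delta-Ct relative quantification
#'
#' Standard 2^(-ddCt) relative expression from qPCR cycle-threshold
#' values. Replicate wells are averaged per (sample, gene); the per-sample
#' delta Ct is the target's mean Ct minus the control gene's mean Ct (with
#' several control genes, the mean of their Cts, i.e. the geometric mean
#' of their expression levels on the Ct scale); delta-delta Ct subtracts
#' the calibrator sample's delta Ct gene-wise, so the calibrator's
#' relative expression is exactly 1.
#'
#' @param ct data.frame with columns sample_id, gene, ct (extra columns
#'   such as treatment_group or replicate_index are carried through by the
#'   caller, not used here).
#' @param control_gene one or more housekeeping gene ids.
#' @param calibrator_sample sample_id used as calibrator.
#' @return data.frame: sample_id, gene (targets only), delta_ct,
#'   delta_delta_ct, rel_expr; samples lacking a control-gene measurement
#'   are dropped and listed in attribute `flagged_samples`.
#' @export
delta_delta_ct <- function(ct, control_gene, calibrator_sample) {
  req <- c("sample_id", "gene", "ct")
  if (!all(req %in% names(ct))) stop("ct table needs columns sample_id, gene, ct")
  if (!all(is.finite(ct$ct)) || any(ct$ct <= 0)) stop("ct values must be finite and positive")
  mean_ct <- stats::aggregate(ct ~ sample_id + gene, data = ct, FUN = mean)
  samples <- unique(mean_ct$sample_id)
  if (!calibrator_sample %in% samples) stop("calibrator sample not found: ", calibrator_sample)
  ctrl <- mean_ct[mean_ct$gene %in% control_gene, , drop = FALSE]
  if (length(unique(ctrl$gene)) < length(unique(control_gene)))
    stop("control gene(s) not measured: ",
         paste(setdiff(control_gene, ctrl$gene), collapse = ", "))
  ctrl_by_sample <- tapply(ctrl$ct, ctrl$sample_id, mean)
  have_ctrl <- names(ctrl_by_sample)[
    table(ctrl$sample_id)[names(ctrl_by_sample)] == length(unique(control_gene))]
  flagged <- setdiff(samples, have_ctrl)
  if (length(flagged))
    warning("no complete control-gene measurement for sample(s): ",
            paste(flagged, collapse = ", "))
  if (!calibrator_sample %in% have_ctrl)
    stop("calibrator sample lacks control-gene measurement")
  targ <- mean_ct[!mean_ct$gene %in% control_gene &
                    mean_ct$sample_id %in% have_ctrl, , drop = FALSE]
  targ$delta_ct <- targ$ct - as.numeric(ctrl_by_sample[targ$sample_id])
  cal <- targ[targ$sample_id == calibrator_sample, c("gene", "delta_ct")]
  targ$delta_delta_ct <- targ$delta_ct -
    cal$delta_ct[match(targ$gene, cal$gene)]
  targ$rel_expr <- 2^(-targ$delta_delta_ct)
  out <- targ[order(targ$gene, targ$sample_id),
              c("sample_id", "gene", "delta_ct", "delta_delta_ct", "rel_expr")]
  rownames(out) <- NULL
  attr(out, "flagged_samples") <- flagged
  out
}

#' Covariate-adjusted linear regression between gene expression levels
#'
#' Ordinary least squares of one gene's expression on another's, adjusted
#' for nuisance covariates. Categorical covariates (e.g. plate) are
#' dummy-coded; a covariate named `rin_centered_squared` that is absent
#' from the data is derived as (rin - mean(rin))^2 with the mean taken
#' over the rows actually fitted, which is the conventional way to let a
#' quality score act curvilinearly without inducing collinearity with its
#' linear term. The predictor gene's coefficient is reported with a
#' two-sided t-test p-value and 95% confidence interval.
#'
#' @param data data.frame holding outcome, predictor and covariates.
#' @param outcome,predictor column names of the two gene-expression levels.
#' @param covariates character vector of covariate column names (may
#'   include "rin_centered_squared" to request the derived term).
#' @return list: beta, se, p, ci_low_95, ci_high_95, n, residual_df, fit.
#' @export
adjusted_regression <- function(data, outcome, predictor, covariates = character()) {
  stopifnot(outcome %in% names(data), predictor %in% names(data))
  derive_rin2 <- "rin_centered_squared" %in% covariates &&
    !"rin_centered_squared" %in% names(data)
  if (derive_rin2 && !"rin" %in% names(data))
    stop("rin column required to derive rin_centered_squared")
  base_cols <- c(outcome, predictor, setdiff(covariates, "rin_centered_squared"),
                 if (derive_rin2) "rin")
  cc <- stats::complete.cases(data[, unique(base_cols), drop = FALSE])
  d <- data[cc, , drop = FALSE]
  if (derive_rin2)
    d$rin_centered_squared <- (d$rin - mean(d$rin))^2
  if (nrow(d) < length(covariates) + 3L)
    stop("too few complete cases for the requested model")
  if (stats::var(d[[outcome]]) == 0) stop("outcome is constant")
  fml <- stats::reformulate(c(sprintf("`%s`", predictor),
                              sprintf("`%s`", covariates)),
                            response = sprintf("`%s`", outcome))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  term <- sprintf("`%s`", predictor)
  if (!term %in% rownames(sm$coefficients)) term <- predictor
  est <- sm$coefficients[term, "Estimate"]
  se <- sm$coefficients[term, "Std. Error"]
  p <- sm$coefficients[term, "Pr(>|t|)"]
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  list(beta = est, se = se, p = p,
       ci_low_95 = est - tcrit * se, ci_high_95 = est + tcrit * se,
       n = nrow(d), residual_df = fit$df.residual, fit = fit)
}

#' Exact two-sided Mann-Whitney U test
#'
#' Exact permutation null of the U statistic: every assignment of the
#' pooled observations to the two groups (respecting group sizes) is
#' equally likely; ties take mid-ranks, contributing 1/2 to U. The exact
#' distribution of the rank sum is built by dynamic programming over the
#' (doubled, hence integer) mid-ranks, which is equivalent to full
#' enumeration of all C(n1+n2, n1) assignments. Two-sided p is
#' 2 * min(lower tail, upper tail), capped at 1. Suitable for the tiny
#' group sizes (e.g. 4 vs 4) where the normal approximation is invalid.
#'
#' @param group1,group2 numeric vectors, each non-empty.
#' @return list(U, p_two_sided); U is the statistic for `group1`
#'   (number of (x, y) pairs with x > y, ties counting 1/2).
#' @export
mann_whitney_exact <- function(group1, group2) {
  x <- as.numeric(group1); y <- as.numeric(group2)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r2 <- as.integer(round(2 * rank(c(x, y))))    # doubled mid-ranks: integers
  rs_obs <- sum(r2[seq_len(n1)])
  # f[k+1, s+1] = number of size-k subsets of the doubled ranks summing to s
  smax <- sum(r2)
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1, 1] <- 1
  for (r in r2) {
    for (k in min(n1, N):1) {         # iterate k downward for 0/1 knapsack
      nz <- which(f[k, ] > 0)
      if (length(nz)) f[k + 1L, nz + r] <- f[k + 1L, nz + r] + f[k, nz]
    }
  }
  dist <- f[n1 + 1L, ]
  total <- sum(dist)                   # = choose(N, n1)
  sums <- which(dist > 0) - 1L
  lower <- sum(dist[sums + 1L][sums <= rs_obs]) / total
  upper <- sum(dist[sums + 1L][sums >= rs_obs]) / total
  U <- (rs_obs - n1 * (n1 + 1L)) / 2   # rs_obs is doubled rank sum
  list(U = U, p_two_sided = min(1, 2 * min(lower, upper)))
}

#' Kruskal-Wallis rank test across treatment groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference
#' distribution on k-1 degrees of freedom (delegates to
#' [stats::kruskal.test()]). The degenerate all-identical case returns
#' H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return list(H, df, p)
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}
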