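toy_ct <- function() {
  # two samples, target gene + control gene, duplicate wells
  data.frame(
    sample_id = rep(c("ctrl_exp1", "trt_exp1"), each = 4),
    gene = rep(rep(c("TARGET", "HPRT"), each = 2), 2),
    ct = c(24.0, 24.2, 23.0, 23.2,      # ctrl: dCt = 24.1 - 23.1 = 1.0
           25.0, 25.2, 23.0, 23.2))    # trt:  dCt = 25.1 - 23.1 = 2.0
}

test_that("delta-delta-Ct normalizes to the calibrator and halves per extra cycle", {
  rel <- delta_delta_ct(toy_ct(), "HPRT", "ctrl_exp1")
  expect_equal(rel$rel_expr[rel$sample_id == "ctrl_exp1"], 1.0)
  # treated sample is one delta-Ct cycle above the calibrator -> 2^-1
  expect_equal(rel$rel_expr[rel$sample_id == "trt_exp1"], 0.5, tolerance = 1e-12)
  expect_equal(rel$delta_ct, c(1.0, 2.0), tolerance = 1e-12)
})

test_that("relative expression is invariant to a global Ct shift", {
  ct <- toy_ct()
  shifted <- ct; shifted$ct <- shifted$ct + 3.7
  expect_equal(delta_delta_ct(shifted, "HPRT", "ctrl_exp1")$rel_expr,
               delta_delta_ct(ct, "HPRT", "ctrl_exp1")$rel_expr,
               tolerance = 1e-12)
})

test_that("two control genes are combined on the Ct scale", {
  ct <- toy_ct()
  gapdh <- ct[ct$gene == "HPRT", ]; gapdh$gene <- "GAPDH"; gapdh$ct <- gapdh$ct + 2
  rel <- delta_delta_ct(rbind(ct, gapdh), c("HPRT", "GAPDH"), "ctrl_exp1")
  # averaging Cts = geometric mean of expression; fold change unchanged
  expect_equal(rel$rel_expr[rel$sample_id == "trt_exp1"], 0.5, tolerance = 1e-12)
})

test_that("samples without control-gene wells are flagged and dropped", {
  ct <- toy_ct()
  ct <- ct[!(ct$sample_id == "trt_exp1" & ct$gene == "HPRT"), ]
  expect_warning(rel <- delta_delta_ct(ct, "HPRT", "ctrl_exp1"), "trt_exp1")
  expect_false("trt_exp1" %in% rel$sample_id)
  expect_equal(attr(rel, "flagged_samples"), "trt_exp1")
})

test_that("planted qPCR fold changes are recovered through the Ct pipeline", {
  set.seed(12)
  hits <- replicate(100, {
    ct <- simulate_ct(c("si_control", "si_kd"),
                      fold_changes = list(TARGET = c(si_control = 1, si_kd = 0.5)),
                      noise_sd = 0.2)
    rel <- delta_delta_ct(ct, "HPRT", attr(ct, "calibrator"))
    rel$rel_expr[rel$sample_id == "si_kd_exp1"]
  })
  expect_lt(abs(mean(hits) - 0.5) / 0.5, 0.10)
  # no-change simulation stays at 1
  ct1 <- simulate_ct(c("a", "b"), list(TARGET = c(a = 1, b = 1)), seed = 3)
  rel1 <- delta_delta_ct(ct1, "HPRT", attr(ct1, "calibrator"))
  expect_lt(abs(rel1$rel_expr[rel1$sample_id == "b_exp1"] - 1), 0.5)
})

test_that("adjusted regression reduces to exact OLS identities", {
  d <- data.frame(y = 1:10 + 0.5, x = 1:10)
  # lm warns about the essentially perfect fit; that is the point here
  r <- suppressWarnings(adjusted_regression(d, "y", "x"))
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_equal(sum(residuals(r$fit)^2), 0, tolerance = 1e-20)
  # beta invariant under outcome shift, scales with outcome scaling
  d2 <- d; d2$y <- d$y + 100
  expect_equal(suppressWarnings(adjusted_regression(d2, "y", "x"))$beta,
               r$beta, tolerance = 1e-10)
  d3 <- d; d3$y <- 2.5 * d$y
  expect_equal(suppressWarnings(adjusted_regression(d3, "y", "x"))$beta,
               2.5 * r$beta, tolerance = 1e-10)
})

test_that("adjusted regression matches the normal-equations oracle", {
  set.seed(19)
  d <- simulate_expression(50, true_beta = 0.4,
                           nuisance = list(diagnosis = 0.5,
                                           markers = c(0.3, -0.2, 0.1, 0, 0.2)),
                           noise_sd = 0.7)
  covs <- c("diagnosis", "age", "sexmale", "rin", "rin_centered_squared",
            "plate", "marker_neuron", "marker_astro", "marker_microglia",
            "marker_oligo", "marker_endo")
  r <- adjusted_regression(d, "outcome", "predictor", covs)
  # normal equations on the same design, built independently
  rin_c2 <- (d$rin - mean(d$rin))^2
  X <- cbind(1, d$predictor, d$diagnosis, d$age, d$sexmale, d$rin, rin_c2,
             model.matrix(~plate, d)[, -1],
             as.matrix(d[, grep("^marker_", names(d))]))
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$outcome)
  expect_equal(r$beta, beta_hat[2], tolerance = 1e-8)
  expect_equal(r$n, 50L)
  # collinear covariate is named in the error
  d$dup <- d$marker_neuron
  expect_error(adjusted_regression(d, "outcome", "predictor", c(covs, "dup")),
               "collinear.*dup")
  expect_error(adjusted_regression(transform(d, outcome = 1), "outcome",
                                   "predictor"), "constant")
})

test_that("exact Mann-Whitney reproduces enumeration and canonical values", {
  # fully separated 4 vs 4: one-sided tail 1/70, two-sided 2/70
  r <- mann_whitney_exact(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_equal(r$p_two_sided, 2 / 70, tolerance = 1e-12)
  expect_equal(round(r$p_two_sided, 2), 0.03)
  expect_equal(r$U, 16)
  # identical groups
  expect_equal(mann_whitney_exact(rep(5, 4), rep(5, 4))$p_two_sided, 1)
  # (3,3): every possible configuration matches exhaustive enumeration
  set.seed(40)
  for (rep in 1:20) {
    x <- sample(1:6, 3); y <- sample(1:6, 3, replace = TRUE)  # with ties
    expect_equal(mann_whitney_exact(x, y)$p_two_sided, mw_oracle(x, y),
                 tolerance = 1e-12)
  }
  # larger unequal groups against enumeration
  x <- c(1.2, 5.5, 3.3, 8.1, 2.2); y <- c(4.4, 6.6, 0.5)
  expect_equal(mann_whitney_exact(x, y)$p_two_sided, mw_oracle(x, y),
               tolerance = 1e-12)
})

test_that("exact Mann-Whitney is symmetric and monotone in separation", {
  x <- c(1, 2, 3, 4); y <- c(2.5, 3.5, 6, 7)
  expect_equal(mann_whitney_exact(x, y)$p_two_sided,
               mann_whitney_exact(y, x)$p_two_sided, tolerance = 1e-12)
  shifts <- c(0, 1, 3, 6, 10)
  ps <- vapply(shifts, function(s)
    mann_whitney_exact(x, y + s)$p_two_sided, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(mann_whitney_exact(numeric(0), y), "non-empty")
})

test_that("Kruskal-Wallis matches the direct rank formula and base R", {
  groups <- list(c(1, 3, 5), c(2, 4, 9), c(7, 8, 10))
  r <- kruskal_wallis(groups)
  # direct formula, no ties: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  v <- unlist(groups); rk <- rank(v); N <- length(v)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, function(z) length(z) * (mean(z) - (N + 1) / 2)^2))
  expect_equal(r$H, H, tolerance = 1e-12)
  expect_equal(r$p, pchisq(H, 2, lower.tail = FALSE), tolerance = 1e-12)
  # degenerate: everything identical
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$H, 0)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p, 1)
  # invariant under strictly monotone transforms
  r2 <- kruskal_wallis(lapply(groups, function(g) exp(g)))
  expect_equal(r2$H, r$H, tolerance = 1e-12)
})

test_that("Kruskal-Wallis on two groups tracks the Mann-Whitney ordering", {
  set.seed(64)
  for (rep in 1:5) {
    x <- rnorm(20); y <- rnorm(20, 0.8)
    kw <- kruskal_wallis(list(x, y))$p
    mw <- mann_whitney_exact(x, y)$p_two_sided
    # both are rank tests of the same shift; p-values agree to within
    # the chi-square approximation error
    expect_lt(abs(log(kw) - log(mw)), 0.7)
  }
})

test_that("planted expression effects land inside their confidence intervals", {
  set.seed(90)
  cover <- replicate(60, {
    d <- simulate_expression(200, true_beta = 0.15,
                             nuisance = list(diagnosis = 0.3,
                                             rin = 0.2, rin2 = -0.05,
                                             plate = c(0, 0.2, -0.1, 0.3),
                                             markers = c(0.3, -0.2, 0.1, 0.05, 0)),
                             noise_sd = 1)
    r <- adjusted_regression(d, "outcome", "predictor",
                             c("diagnosis", "rin", "rin_centered_squared",
                               "plate", "marker_neuron", "marker_astro",
                               "marker_microglia", "marker_oligo", "marker_endo"))
    r$ci_low_95 <= 0.15 && 0.15 <= r$ci_high_95
  })
  expect_gte(mean(cover), 0.85)
  expect_lte(mean(cover), 1.00)
})
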