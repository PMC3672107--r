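test_that("EM reduces to direct gamete counting without double heterozygotes", {
  # no (1,1) genotype: phase is unambiguous
  d1 <- c(0, 0, 1, 2, 2, 0, 1, 2)
  d2 <- c(0, 1, 2, 0, 2, 0, 0, 1)
  h <- em_two_locus(d1, d2)
  # unique phase means EM must equal direct gamete counting
  cnt <- table(factor(d1, 0:2), factor(d2, 0:2))
  n <- length(d1)
  pAB <- (2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]) / (2 * n)
  pAb <- (2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]) / (2 * n)
  paB <- (2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3]) / (2 * n)
  expect_equal(h$p_AB, unname(pAB), tolerance = 1e-9)
  expect_equal(h$p_Ab, unname(pAb), tolerance = 1e-9)
  expect_equal(h$p_aB, unname(paB), tolerance = 1e-9)
  expect_true(h$converged)
})

test_that("identical dosage columns give complete LD", {
  d <- c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2)
  h <- em_two_locus(d, d)
  maf <- mean(d) / 2
  expect_equal(h$p_AB, maf, tolerance = 1e-7)
  expect_equal(h$p_ab, 1 - maf, tolerance = 1e-7)
  expect_equal(h$p_Ab, 0, tolerance = 1e-7)
  expect_equal(h$p_aB, 0, tolerance = 1e-7)
  ld <- dprime_r2(h)
  expect_equal(ld$dprime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
})

test_that("EM log-likelihood matches dense grid-search ML on ambiguous fixtures", {
  set.seed(3)
  pool <- default_haplotype_pool()
  for (rep in 1:5) {
    g <- simulate_genotypes(pool, 20)
    pair <- sample(8, 2)
    d1 <- g$dosage[, pair[1]]; d2 <- g$dosage[, pair[2]]
    if (length(unique(d1)) < 2 || length(unique(d2)) < 2) next
    h <- em_two_locus(d1, d2)
    expect_equal(h$log_likelihood, em_grid_oracle(d1, d2), tolerance = 1e-6)
  }
})

test_that("EM log-likelihood is monotone and frequencies sum to one", {
  set.seed(9)
  pool <- default_haplotype_pool()
  for (rep in 1:10) {
    g <- simulate_genotypes(pool, 50)
    pair <- sample(8, 2)
    h <- em_two_locus(g$dosage[, pair[1]], g$dosage[, pair[2]])
    if (h$degenerate) next
    expect_equal(h$p_AB + h$p_Ab + h$p_aB + h$p_ab, 1, tolerance = 1e-9)
    if (length(h$loglik_trace) > 1)
      expect_true(all(diff(h$loglik_trace) >= -1e-10))
  }
})

test_that("monomorphic locus yields a degenerate flagged result", {
  h <- em_two_locus(rep(0, 10), c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0))
  expect_true(h$degenerate)
  ld <- dprime_r2(h)
  expect_false(ld$defined)
  expect_true(is.na(ld$dprime))
})

test_that("D' and r2 evaluate the closed-form definitions", {
  h <- list(p_AB = 0.4, p_Ab = 0.1, p_aB = 0.3, p_ab = 0.2)
  ld <- dprime_r2(h)
  # D = 0.4 - 0.5*0.7 = 0.05; Dmax = min(0.5*0.3, 0.5*0.7) = 0.15
  expect_equal(ld$dprime, 1 / 3, tolerance = 1e-9)
  expect_equal(ld$r2, 0.05^2 / (0.5 * 0.5 * 0.7 * 0.3), tolerance = 1e-9)
  expect_equal(ld$r2, 0.0476, tolerance = 1e-3)
  # independence
  h0 <- list(p_AB = 0.35, p_Ab = 0.35, p_aB = 0.15, p_ab = 0.15)
  ld0 <- dprime_r2(h0)
  expect_equal(ld0$dprime, 0, tolerance = 1e-12)
  expect_equal(ld0$r2, 0, tolerance = 1e-12)
  # complete LD
  h1 <- list(p_AB = 0.3, p_Ab = 0, p_aB = 0, p_ab = 0.7)
  expect_equal(dprime_r2(h1)$dprime, 1)
  expect_equal(dprime_r2(h1)$r2, 1)
})

test_that("D' and r2 are invariant under relabeling the minor allele", {
  set.seed(21)
  pool <- default_haplotype_pool()
  g <- simulate_genotypes(pool, 300)
  d1 <- g$dosage[, 1]; d2 <- g$dosage[, 6]
  ld <- dprime_r2(em_two_locus(d1, d2))
  ld_flip1 <- dprime_r2(em_two_locus(2L - d1, d2))
  ld_flip2 <- dprime_r2(em_two_locus(d1, 2L - d2))
  expect_equal(ld_flip1$dprime, ld$dprime, tolerance = 1e-6)
  expect_equal(ld_flip1$r2, ld$r2, tolerance = 1e-6)
  expect_equal(ld_flip2$dprime, ld$dprime, tolerance = 1e-6)
  expect_equal(ld_flip2$r2, ld$r2, tolerance = 1e-6)
})

test_that("pairwise LD matrix is symmetric with unit diagonal and matches the pair loop", {
  set.seed(5)
  g <- simulate_genotypes(default_haplotype_pool(), 120)
  ld <- pairwise_ld_matrix(g)
  expect_equal(ld$dprime, t(ld$dprime))
  expect_equal(unname(diag(ld$dprime)), rep(1, 8))
  expect_equal(unname(diag(ld$r2)), rep(1, 8))
  for (i in c(1, 3)) for (j in c(5, 8)) {
    ref <- dprime_r2(em_two_locus(g$dosage[, i], g$dosage[, j]))
    expect_equal(ld$dprime[i, j], ref$dprime, tolerance = 1e-12)
    expect_equal(ld$r2[i, j], ref$r2, tolerance = 1e-12)
  }
})

test_that("solid-spine blocks handle canonical configurations", {
  # all pairs in strong LD -> one block over all 5 SNPs
  m1 <- matrix(1, 5, 5)
  b1 <- solid_spine_blocks(m1)
  expect_equal(nrow(b1), 1L)
  expect_equal(c(b1$start, b1$end), c(1L, 5L))
  # SNP 4 in weak LD with everything -> excluded from any block
  m2 <- matrix(1, 6, 6); m2[4, ] <- 0.2; m2[, 4] <- 0.2; diag(m2) <- 1
  b2 <- solid_spine_blocks(m2)
  expect_true(all(vapply(seq_len(nrow(b2)), function(k)
    !(4 %in% (b2$start[k]:b2$end[k])), logical(1))))
  expect_equal(nrow(b2), 2L)   # 1-3 and 5-6
  # single SNP: no block possible
  expect_equal(nrow(solid_spine_blocks(matrix(1, 1, 1))), 0L)
  # undefined entries treated as below threshold
  m3 <- matrix(1, 3, 3); m3[1, 3] <- m3[3, 1] <- NA
  b3 <- solid_spine_blocks(m3)
  expect_equal(nrow(b3), 1L)
  expect_equal(c(b3$start[1], b3$end[1]), c(1L, 2L))
})

test_that("spine blocks mirror under reversal of SNP order", {
  set.seed(13)
  pool <- flanked_block_pool(n_flank = 2)
  g <- simulate_genotypes(pool, 400)
  dp <- pairwise_ld_matrix(g)$dprime
  m <- nrow(dp)
  fwd <- solid_spine_blocks(dp)
  rev_dp <- dp[m:1, m:1]
  bwd <- solid_spine_blocks(rev_dp)
  mirrored <- data.frame(start = m + 1L - rev(bwd$end),
                         end = m + 1L - rev(bwd$start))
  expect_equal(fwd$start, mirrored$start)
  expect_equal(fwd$end, mirrored$end)
})

test_that("estimated D' converges to the pool's theoretical D'", {
  pool <- default_haplotype_pool()
  truth <- pool_ld(pool)
  off <- upper.tri(truth$dprime)
  set.seed(2024)
  # per-pair error is dominated by sampling noise for near-zero D' pairs,
  # so compare the per-pair median over replicates against the pool truth
  errs <- replicate(5, {
    est <- pairwise_ld_matrix(simulate_genotypes(pool, 2000))
    est$dprime[off] - truth$dprime[off]
  })
  med_err <- apply(abs(errs), 1, stats::median)
  expect_true(all(med_err < 0.05))
})
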