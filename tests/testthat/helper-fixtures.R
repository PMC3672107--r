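# Shared fixture builders and independent oracles.

# Build a genotype_matrix directly from allele matrices (bypasses PED IO).
make_geno <- function(a1, a2, diagnosis = NULL, snp_ids = NULL,
                      positions = NULL) {
  n <- nrow(a1); m <- ncol(a1)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%02d", seq_len(m))
  if (is.null(positions)) positions <- 1000L * seq_len(m)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    diagnosis = if (is.null(diagnosis))
      factor(rep(NA_character_, n), levels = c("control", "case"))
    else factor(diagnosis, levels = c("control", "case")),
    stringsAsFactors = FALSE)
  variants <- data.frame(snp_id = snp_ids, chromosome = "10",
                         position = positions, stringsAsFactors = FALSE)
  genotype_matrix(NULL, variants, subjects, alleles = list(a1 = a1, a2 = a2))
}

# Allele matrices from a dosage matrix (minor = "G", major = "A").
alleles_from_dosage <- function(dos) {
  a1 <- ifelse(is.na(dos), NA, ifelse(dos >= 1, "G", "A"))
  a2 <- ifelse(is.na(dos), NA, ifelse(dos == 2, "G", "A"))
  list(a1 = matrix(a1, nrow(dos)), a2 = matrix(a2, nrow(dos)))
}

# Write a tiny PED/MAP pair; genos is a list of per-subject strings like
# c("A A", "G G"), one element per subject, alleles in MAP variant order.
write_toy_ped_map <- function(dir, genos, phenos = NULL, map = NULL) {
  n <- length(genos)
  m <- length(strsplit(genos[[1]], " ")[[1]]) / 2
  if (is.null(phenos)) phenos <- rep(1, n)
  if (is.null(map))
    map <- data.frame(chr = "10", snp = sprintf("rs%d", seq_len(m)),
                      cm = 0, pos = 1000 * seq_len(m))
  ped_path <- file.path(dir, "toy.ped")
  map_path <- file.path(dir, "toy.map")
  lines <- vapply(seq_len(n), function(i)
    paste("FAM", paste0("IND", i), 0, 0, 1, phenos[i], genos[[i]]),
    character(1))
  writeLines(lines, ped_path)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  c(ped = ped_path, map = map_path)
}

# A pool whose 8 block SNPs are in complete pairwise LD (3 haplotypes,
# any SNP pair shows at most 3 of the 4 gametes).
high_ld_block_pool <- function(block_freqs = c(0.5, 0.3, 0.2)) {
  h <- rbind(rep(0, 8),
             rep(1, 8),
             c(1, 1, 1, 1, 0, 0, 0, 0))
  haplotype_pool(h, block_freqs)
}

# Product pool: high-LD 8-SNP block flanked by `n_flank` independent SNPs
# on each side (allele-1 frequency `p_flank`).
flanked_block_pool <- function(n_flank = 2, p_flank = 0.3,
                               block_freqs = c(0.5, 0.3, 0.2)) {
  blk <- high_ld_block_pool(block_freqs)
  k <- 2 * n_flank
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  hap_list <- list(); freqs <- numeric(0)
  for (i in seq_len(nrow(blk$haplotypes))) {
    for (j in seq_len(nrow(combos))) {
      left <- combos[j, seq_len(n_flank), drop = TRUE]
      right <- combos[j, n_flank + seq_len(n_flank), drop = TRUE]
      hap_list[[length(hap_list) + 1L]] <- c(left, blk$haplotypes[i, ], right)
      pf <- prod(ifelse(combos[j, ] == 1, p_flank, 1 - p_flank))
      freqs <- c(freqs, blk$freqs[i] * pf)
    }
  }
  haplotype_pool(do.call(rbind, hap_list), freqs)
}

# --- independent oracles -------------------------------------------------

# HWE: exact conditional probabilities from the closed-form hypergeometric
# count (multinomial arrangements over a fixed allele pool), normalized by
# choose(2n, n_minor) analytically rather than empirically.
hwe_oracle <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  n_minor <- 2 * n_hom_minor + n_het
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  logp <- sapply(hets, function(h) {
    mi <- (n_minor - h) / 2; ma <- n - mi - h
    lfactorial(n) - lfactorial(mi) - lfactorial(h) - lfactorial(ma) +
      h * log(2) - lchoose(2 * n, n_minor)
  })
  pr <- exp(logp)
  p_obs <- pr[hets == n_het]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# Mann-Whitney: exhaustive enumeration over all C(N, n1) group assignments.
mw_oracle <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  rs_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(N, n1)
  rs <- apply(sets, 2, function(s) sum(r[s]))
  min(1, 2 * min(mean(rs <= rs_obs + 1e-9), mean(rs >= rs_obs - 1e-9)))
}

# Two-locus ML by dense grid search over the one free haplotype frequency
# (allele-frequency margins are fixed at their sample values).
em_grid_oracle <- function(d1, d2, grid_n = 200001L) {
  ok <- !is.na(d1) & !is.na(d2)
  d1 <- d1[ok]; d2 <- d2[ok]
  pA <- mean(d1) / 2; pB <- mean(d2) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  cnt <- table(factor(d1, 0:2), factor(d2, 0:2))
  ll <- function(pAB) {
    p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    pr <- matrix(c(p[4]^2, 2 * p[4] * p[3], p[3]^2,
                   2 * p[2] * p[4], 2 * (p[1] * p[4] + p[2] * p[3]), 2 * p[1] * p[3],
                   p[2]^2, 2 * p[1] * p[2], p[1]^2), 3, 3, byrow = TRUE)
    sum(ifelse(cnt > 0, cnt * log(pr), 0))
  }
  max(vapply(seq(lo, hi, length.out = grid_n), ll, numeric(1)))
}

# Logistic log-likelihood maximized by a derivative-free optimizer.
logistic_optim_oracle <- function(X, y) {
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(X)), negll, method = "Nelder-Mead",
                      control = list(maxit = 50000, reltol = 1e-14))
  fit2 <- stats::optim(fit$par, negll, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))
  -min(fit$value, fit2$value)
}
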