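#' Two-locus haplotype frequencies by EM from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci
#' from unphased dosage data. Phase is ambiguous only for double
#' heterozygotes; the EM algorithm splits those between the AB/ab and
#' Ab/aB resolutions in proportion to the current frequency estimates.
#' Alleles A and B denote the minor alleles the dosages count.
#'
#' Starting point is linkage equilibrium (product of the observed allele
#' frequencies); iteration stops when the largest frequency change drops
#' below `tol` or after `max_iter` iterations (non-convergence is flagged,
#' the last estimate is still returned).
#'
#' @param d1,d2 integer dosage vectors (0/1/2, NA = missing) at the two loci.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter iteration cap.
#' @return object of class `two_locus_haps`: p_AB, p_Ab, p_aB, p_ab,
#'   log_likelihood, loglik_trace, n_iter, converged, n (complete pairs),
#'   degenerate (TRUE when a locus is monomorphic, D undefined).
#' @export
em_two_locus <- function(d1, d2, tol = 1e-8, max_iter = 1000L) {
  ok <- !is.na(d1) & !is.na(d2)
  d1 <- as.integer(d1[ok]); d2 <- as.integer(d2[ok])
  n <- length(d1)
  if (n < 2L) stop("need at least 2 subjects with complete data at both loci")
  if (!all(d1 %in% 0:2) || !all(d2 %in% 0:2)) stop("dosages must be 0, 1 or 2")
  pA <- mean(d1) / 2; pB <- mean(d2) / 2
  res <- list(p_AB = NA_real_, p_Ab = NA_real_, p_aB = NA_real_, p_ab = NA_real_,
              log_likelihood = NA_real_, loglik_trace = numeric(0),
              n_iter = 0L, converged = FALSE, n = n, degenerate = FALSE,
              p_A = pA, p_B = pB)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    res$degenerate <- TRUE
    res$p_AB <- pA * pB; res$p_Ab <- pA * (1 - pB)
    res$p_aB <- (1 - pA) * pB; res$p_ab <- (1 - pA) * (1 - pB)
    res$converged <- TRUE
    class(res) <- "two_locus_haps"
    return(res)
  }
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[d1[i] + 1L, d2[i] + 1L] <- cnt[d1[i] + 1L, d2[i] + 1L] + 1
  # unambiguous gamete counts; row/col index = dosage + 1
  # haplotype order: AB, Ab, aB, ab
  base <- c(
    AB = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
    Ab = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
    aB = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
    ab = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1])
  ndh <- cnt[2, 2]                       # double heterozygotes
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  loglik <- function(p) {
    pr <- c(p[4]^2, 2 * p[4] * p[3], p[3]^2,
            2 * p[2] * p[4], 2 * (p[1] * p[4] + p[2] * p[3]), 2 * p[1] * p[3],
            p[2]^2, 2 * p[1] * p[2], p[1]^2)
    obs <- c(cnt[1, 1], cnt[1, 2], cnt[1, 3], cnt[2, 1], cnt[2, 2], cnt[2, 3],
             cnt[3, 1], cnt[3, 2], cnt[3, 3])
    sum(ifelse(obs > 0, obs * log(pr), 0))
  }
  trace <- numeric(0)
  converged <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    e <- base + ndh * c(w, 1 - w, 1 - w, w)
    p_new <- e / (2 * n)
    trace <- c(trace, loglik(p_new))
    if (max(abs(p_new - p)) < tol) { p <- p_new; converged <- TRUE; break }
    p <- p_new
    if (it >= max_iter) break
  }
  p <- unname(p)
  res$p_AB <- p[1]; res$p_Ab <- p[2]; res$p_aB <- p[3]; res$p_ab <- p[4]
  res$log_likelihood <- loglik(p)
  res$loglik_trace <- trace
  res$n_iter <- it; res$converged <- converged
  class(res) <- "two_locus_haps"
  res
}

#' @export
print.two_locus_haps <- function(x, ...) {
  cat(sprintf("two-locus haplotype frequencies (n = %d)\n", x$n))
  cat(sprintf("  AB %.4f  Ab %.4f  aB %.4f  ab %.4f\n",
              x$p_AB, x$p_Ab, x$p_aB, x$p_ab))
  if (x$degenerate) cat("  degenerate (monomorphic locus); D undefined\n")
  invisible(x)
}

#' D' and r-squared from two-locus haplotype frequencies
#'
#' D = p_AB - p_A p_B; D' = |D| / Dmax with
#' Dmax = min(p_A p_b, p_a p_B) for D > 0 and min(p_A p_B, p_a p_b)
#' for D < 0; r2 = D^2 / (p_A p_a p_B p_b). Undefined (flagged) when any
#' marginal allele frequency is 0 or 1.
#'
#' @param h two_locus_haps object (or list with p_AB..p_ab).
#' @return list(dprime, r2, d, defined)
#' @export
dprime_r2 <- function(h) {
  pA <- h$p_AB + h$p_Ab; pB <- h$p_AB + h$p_aB
  pa <- 1 - pA; pb <- 1 - pB
  if (isTRUE(h$degenerate) || min(pA, pa, pB, pb) <= 0)
    return(list(dprime = NA_real_, r2 = NA_real_, d = NA_real_, defined = FALSE))
  d <- unname(h$p_AB - pA * pB)
  dmax <- if (d > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  dprime <- if (d == 0) 0 else abs(d) / dmax
  r2 <- d^2 / (pA * pa * pB * pb)
  list(dprime = min(dprime, 1), r2 = min(r2, 1), d = d, defined = TRUE)
}

#' Pairwise LD matrices over all variants
#'
#' Runs [em_two_locus()] + [dprime_r2()] for every variant pair of a
#' (typically QC'd) genotype matrix. Diagonal entries are 1; undefined
#' pairs (monomorphic locus) propagate as NA.
#'
#' @param g recoded genotype_matrix.
#' @return list of symmetric matrices `dprime` and `r2` with snp_id dimnames.
#' @export
pairwise_ld_matrix <- function(g) {
  if (is.null(g$dosage)) stop("genotypes must be minor-allele coded first")
  m <- n_variants(g)
  dp <- matrix(NA_real_, m, m, dimnames = list(g$variants$snp_id, g$variants$snp_id))
  r2 <- dp
  diag(dp) <- 1; diag(r2) <- 1
  if (m < 2L) return(list(dprime = dp, r2 = r2))
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      ld <- dprime_r2(em_two_locus(g$dosage[, i], g$dosage[, j]))
      dp[i, j] <- dp[j, i] <- ld$dprime
      r2[i, j] <- r2[j, i] <- ld$r2
    }
  }
  list(dprime = dp, r2 = r2)
}

#' Solid-spine-of-LD haplotype blocks
#'
#' A run of map-ordered variants i..j forms a solid spine when the two
#' flanking variants are in strong LD (D' at or above the threshold) with
#' each other and with every intermediate variant. Blocks are grown
#' greedily left to right: from each starting index the longest valid run
#' is taken, the scan resumes after it, so blocks never overlap; a block
#' needs at least 2 variants. Undefined D' entries count as below
#' threshold.
#'
#' @param dprime symmetric D' matrix over map-ordered variants (from
#'   [pairwise_ld_matrix()]), or the list that function returns.
#' @param dprime_threshold strong-LD threshold (default 0.8).
#' @return data.frame of class `ld_blocks`: start, end (1-based inclusive
#'   variant indices), n_snps; threshold kept as attribute.
#' @export
solid_spine_blocks <- function(dprime, dprime_threshold = 0.8) {
  if (is.list(dprime) && !is.null(dprime$dprime)) dprime <- dprime$dprime
  dprime <- as.matrix(dprime)
  if (nrow(dprime) != ncol(dprime)) stop("D' matrix must be square")
  m <- nrow(dprime)
  strong <- !is.na(dprime) & dprime >= dprime_threshold
  valid <- function(i, j) {
    if (!strong[i, j]) return(FALSE)
    if (j - i >= 2) {
      k <- (i + 1):(j - 1)
      if (!all(strong[i, k] & strong[k, j])) return(FALSE)
    }
    TRUE
  }
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i < m) {
    jbest <- 0L
    for (j in m:(i + 1L)) if (valid(i, j)) { jbest <- j; break }
    if (jbest > 0L) {
      starts <- c(starts, i); ends <- c(ends, jbest)
      i <- jbest + 1L
    } else i <- i + 1L
  }
  out <- data.frame(start = starts, end = ends, n_snps = ends - starts + 1L)
  attr(out, "dprime_threshold") <- dprime_threshold
  class(out) <- c("ld_blocks", "data.frame")
  out
}

#' Write a D' matrix as TSV
#' @param ld list from [pairwise_ld_matrix()] or a matrix
#' @param path output path
#' @export
write_dprime_matrix <- function(ld, path) {
  m <- if (is.list(ld) && !is.null(ld$dprime)) ld$dprime else as.matrix(ld)
  utils::write.table(data.frame(snp_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detected blocks as a BED-like TSV
#'
#' One row per block: chromosome, 1-based start and (inclusive) end map
#' positions, number of SNPs and comma-joined snp ids.
#' @param blocks ld_blocks data.frame
#' @param variants variant table of the matrix the blocks were detected on
#' @param path output path
#' @export
write_blocks <- function(blocks, variants, path) {
  rows <- lapply(seq_len(nrow(blocks)), function(b) {
    idx <- blocks$start[b]:blocks$end[b]
    data.frame(chromosome = variants$chromosome[blocks$start[b]],
               start_pos = variants$position[blocks$start[b]],
               end_pos = variants$position[blocks$end[b]],
               n_snps = length(idx),
               snp_ids = paste(variants$snp_id[idx], collapse = ","))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
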