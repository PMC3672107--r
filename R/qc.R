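#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic locus. Given observed genotype
#' counts, all heterozygote counts compatible with the observed allele
#' counts are enumerated; under the null every gamete arrangement is
#' equally likely, giving the hypergeometric-type conditional distribution
#'
#'   P(n_het | n, n_minor) = C-norm * n! / (n_hom_minor! n_het! n_hom_major!) * 2^n_het
#'
#' and the two-sided p-value sums the probabilities of all configurations
#' whose probability does not exceed that of the observed one.
#'
#' @param n_hom_minor,n_het,n_hom_major non-negative integer genotype counts
#'   (minor-allele homozygotes, heterozygotes, major-allele homozygotes).
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  cnt <- c(n_hom_minor, n_het, n_hom_major)
  if (length(cnt) != 3L || anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n < 1) stop("at least one genotyped subject required")
  n_minor <- 2L * n_hom_minor + n_het
  # enumerate heterozygote counts with the parity of the minor-allele count
  het_max <- min(n_minor, 2L * n - n_minor)
  hets <- seq.int(n_minor %% 2L, het_max, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_mi <- (n_minor - h) %/% 2L
    hom_ma <- n - hom_mi - h
    h * log(2) + lfactorial(n) -
      lfactorial(hom_mi) - lfactorial(h) - lfactorial(hom_ma)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Apply variant quality-control filters
#'
#' Retains variants with minor allele frequency strictly above `maf_min`,
#' call rate strictly above `call_rate_min`, and exact Hardy-Weinberg
#' p-value in controls strictly above `hwe_p_min`. The strict inequalities
#' mirror the usual reporting convention ("MAF > 0.01, genotyping rate
#' > 90%, HWE p > 0.0001 in controls"). When the dataset contains no
#' diagnosed controls the HWE filter is skipped and the report says so.
#'
#' @param g recoded genotype_matrix (see [recode_minor_allele()]).
#' @param maf_min,call_rate_min,hwe_p_min filter thresholds.
#' @return list with elements `genotypes` (filtered genotype_matrix) and
#'   `report` (per-variant data.frame: snp_id, maf, call_rate,
#'   hwe_p_controls, pass, reasons).
#' @export
apply_qc <- function(g, maf_min = 0.01, call_rate_min = 0.90,
                     hwe_p_min = 0.0001) {
  if (is.null(g$dosage)) stop("genotypes must be minor-allele coded first")
  m <- n_variants(g)
  controls <- which(!is.na(g$subjects$diagnosis) &
                      g$subjects$diagnosis == "control")
  hwe_skipped <- length(controls) == 0L
  if (hwe_skipped)
    warning("no diagnosed controls: HWE filter skipped")
  maf <- g$variants$maf
  call_rate <- g$variants$call_rate
  hwe_p <- rep(NA_real_, m)
  if (!hwe_skipped) {
    for (j in seq_len(m)) {
      d <- g$dosage[controls, j]
      d <- d[!is.na(d)]
      if (length(d) == 0L) next
      hwe_p[j] <- hwe_exact_test(sum(d == 2L), sum(d == 1L), sum(d == 0L))
    }
  }
  reasons <- character(m)
  fail_maf <- !(maf > maf_min)
  fail_cr <- !(call_rate > call_rate_min)
  fail_hwe <- if (hwe_skipped) rep(FALSE, m) else !(hwe_p > hwe_p_min)
  fail_hwe[is.na(fail_hwe)] <- TRUE
  if (hwe_skipped) fail_hwe[] <- FALSE
  for (j in seq_len(m)) {
    r <- c(if (fail_maf[j]) sprintf("maf<=%.4g", maf_min),
           if (fail_cr[j]) sprintf("call_rate<=%.4g", call_rate_min),
           if (fail_hwe[j]) sprintf("hwe_p<=%.4g", hwe_p_min),
           if (hwe_skipped) "hwe_skipped_no_controls")
    reasons[j] <- paste(r, collapse = ";")
  }
  pass <- !(fail_maf | fail_cr | fail_hwe)
  report <- data.frame(snp_id = g$variants$snp_id, maf = maf,
                       call_rate = call_rate, hwe_p_controls = hwe_p,
                       pass = pass, reasons = reasons,
                       stringsAsFactors = FALSE)
  keep <- which(pass)
  filt <- genotype_matrix(
    g$dosage[, keep, drop = FALSE],
    g$variants[keep, , drop = FALSE],
    g$subjects,
    alleles = if (!is.null(g$alleles))
      lapply(g$alleles, function(a) a[, keep, drop = FALSE]))
  list(genotypes = filt, report = report)
}

#' Write a QC report TSV
#' @param report data.frame from [apply_qc()]
#' @param path output path
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
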