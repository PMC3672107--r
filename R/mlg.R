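#' Assign multilocus genotypes (MLGs) for a block of SNPs
#'
#' An MLG is the combination of minor-allele counts across the SNPs of a
#' block: each locus contributes a digit 0, 1 or 2, concatenated in map
#' order behind the prefix "MLG" (e.g. dosages 1,1,0,1,0,1,1,1 over an
#' 8-SNP block give "MLG11010111"). Subjects missing a genotype at any
#' block SNP are excluded from the block and tallied separately. The
#' reference MLG is the most frequent one among subjects with a known
#' diagnosis, ties broken lexicographically by label.
#'
#' @param g recoded genotype_matrix.
#' @param block integer vector of variant indices (map order), or an
#'   `ld_blocks` row via `block = c(start, end)` expanded by the caller.
#' @return object of class `mlg_assignment`: per-subject `labels` (NA for
#'   excluded), `counts` table (mlg, n_control, n_case, n_total),
#'   `reference`, `rare_members` (empty until [group_rare()]),
#'   `n_excluded_missing`, `snp_ids`.
#' @export
assign_mlgs <- function(g, block) {
  if (is.null(g$dosage)) stop("genotypes must be minor-allele coded first")
  block <- as.integer(block)
  if (length(block) == 0L) stop("block must contain at least one variant")
  if (any(block < 1L | block > n_variants(g))) stop("block index out of range")
  d <- g$dosage[, block, drop = FALSE]
  complete <- rowSums(is.na(d)) == 0L
  labels <- rep(NA_character_, nrow(d))
  if (any(complete))
    labels[complete] <- paste0("MLG", apply(d[complete, , drop = FALSE], 1,
                                            paste, collapse = ""))
  diag_ok <- complete & !is.na(g$subjects$diagnosis)
  tab <- table(mlg = labels[diag_ok], diagnosis = g$subjects$diagnosis[diag_ok])
  counts <- data.frame(
    mlg = rownames(tab),
    n_control = as.integer(if ("control" %in% colnames(tab)) tab[, "control"] else 0L),
    n_case = as.integer(if ("case" %in% colnames(tab)) tab[, "case"] else 0L),
    stringsAsFactors = FALSE)
  counts$n_total <- counts$n_control + counts$n_case
  counts <- counts[order(counts$mlg), , drop = FALSE]
  rownames(counts) <- NULL
  if (nrow(counts) == 0L) stop("no subject has complete genotypes and a diagnosis in this block")
  best <- counts$mlg[counts$n_total == max(counts$n_total)]
  structure(list(labels = stats::setNames(labels, g$subjects$subject_id),
                 counts = counts,
                 reference = sort(best)[1],
                 rare_members = character(0),
                 rare_min_total = NA_integer_,
                 n_excluded_missing = sum(!complete),
                 block = block,
                 snp_ids = g$variants$snp_id[block]),
            class = "mlg_assignment")
}

#' @export
print.mlg_assignment <- function(x, ...) {
  cat("MLG assignment over", length(x$block), "SNPs:",
      paste(x$snp_ids, collapse = ", "), "\n")
  cat("  ", nrow(x$counts), "distinct MLGs;", x$n_excluded_missing,
      "subjects excluded for missing genotypes\n")
  cat("  reference:", x$reference, "\n")
  if (length(x$rare_members))
    cat("  MLG-rare pools", length(x$rare_members), "labels (total count <",
        x$rare_min_total, ")\n")
  invisible(x)
}

#' Pool rare MLGs into an "MLG-rare" category
#'
#' MLGs whose combined case+control count falls below `min_total` are
#' merged into a single "MLG-rare" label; merged counts are the sums over
#' members and the member list is retained. The threshold is applied to
#' the dataset the assignment was built on (pass a combined-cohort
#' assignment to reproduce pooled-study grouping).
#'
#' @param a mlg_assignment from [assign_mlgs()].
#' @param min_total minimum total count to keep an MLG separate (default 10;
#'   an MLG with total exactly `min_total` is kept).
#' @return mlg_assignment with merged counts and relabelled subjects.
#' @export
group_rare <- function(a, min_total = 10L) {
  stopifnot(inherits(a, "mlg_assignment"))
  rare <- a$counts$mlg[a$counts$n_total < min_total]
  if (length(rare) == 0L) {
    a$rare_min_total <- as.integer(min_total)
    return(a)
  }
  keep <- a$counts[!a$counts$mlg %in% rare, , drop = FALSE]
  pooled <- data.frame(mlg = "MLG-rare",
                       n_control = sum(a$counts$n_control[a$counts$mlg %in% rare]),
                       n_case = sum(a$counts$n_case[a$counts$mlg %in% rare]),
                       stringsAsFactors = FALSE)
  pooled$n_total <- pooled$n_control + pooled$n_case
  a$counts <- rbind(keep, pooled)
  rownames(a$counts) <- NULL
  a$labels[a$labels %in% rare] <- "MLG-rare"
  a$rare_members <- sort(rare)
  a$rare_min_total <- as.integer(min_total)
  if (a$reference %in% rare)
    stop("reference MLG fell below the rare threshold; dataset too sparse")
  a
}

#' MLG count and within-group frequency table
#'
#' Per-MLG counts with relative frequencies computed within diagnosis
#' group, the denominator being the number of subjects in that group with
#' complete block genotypes. Frequencies are rounded to 3 decimals for
#' reporting (raw frequencies are kept in `freq_*_raw`).
#'
#' @param a mlg_assignment (rare grouping optional).
#' @return data.frame: mlg, n_control, freq_control, n_case, freq_case
#'   plus unrounded columns.
#' @export
mlg_frequency_table <- function(a) {
  stopifnot(inherits(a, "mlg_assignment"))
  tot_con <- sum(a$counts$n_control)
  tot_cas <- sum(a$counts$n_case)
  if (tot_con == 0L || tot_cas == 0L)
    stop("both diagnosis groups must contain subjects")
  fc <- a$counts$n_control / tot_con
  fa <- a$counts$n_case / tot_cas
  data.frame(mlg = a$counts$mlg,
             n_control = a$counts$n_control, freq_control = round(fc, 3),
             n_case = a$counts$n_case, freq_case = round(fa, 3),
             freq_control_raw = fc, freq_case_raw = fa,
             stringsAsFactors = FALSE)
}
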