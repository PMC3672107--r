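#' Genotype matrix container
#'
#' Bundles a subjects-by-variants minor-allele dosage matrix with variant
#' metadata (map order) and subject records. Dosage entries count copies of
#' the variant's minor allele (0/1/2); missing genotypes are `NA`. Objects
#' fresh from [read_ped_map()] carry raw allele pairs and no dosage until
#' [recode_minor_allele()] is applied.
#'
#' @param dosage integer matrix (subjects x variants) in {0,1,2,NA}, or NULL.
#' @param variants data.frame with at least snp_id, chromosome, position;
#'   after recoding also allele_a, allele_b, minor_allele, maf, call_rate,
#'   monomorphic.
#' @param subjects data.frame with at least subject_id; diagnosis is a
#'   factor with levels control/case when known.
#' @param alleles optional list of two character matrices (a1, a2) holding
#'   the raw allele symbols; NA where the genotype is missing.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, subjects, alleles = NULL) {
  stopifnot(is.data.frame(variants), is.data.frame(subjects))
  if (!all(c("snp_id", "chromosome", "position") %in% names(variants)))
    stop("variants must have snp_id, chromosome and position columns")
  if (!"subject_id" %in% names(subjects))
    stop("subjects must have a subject_id column")
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in subjects")
  if (!is.null(dosage)) {
    dosage <- as.matrix(dosage)
    if (nrow(dosage) != nrow(subjects) || ncol(dosage) != nrow(variants))
      stop("dosage dimensions do not match subjects x variants")
    bad <- !(dosage %in% c(0L, 1L, 2L, NA))
    if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
    dimnames(dosage) <- list(subjects$subject_id, variants$snp_id)
  }
  ord <- order(variants$chromosome, variants$position)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    if (!is.null(dosage)) dosage <- dosage[, ord, drop = FALSE]
    if (!is.null(alleles)) alleles <- lapply(alleles, function(m) m[, ord, drop = FALSE])
  }
  structure(list(dosage = dosage, variants = variants, subjects = subjects,
                 alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$subjects), "subjects x",
      nrow(x$variants), "variants\n")
  if (is.null(x$dosage)) cat("  raw alleles only (not yet minor-allele coded)\n")
  if (!is.null(x$subjects$diagnosis)) {
    tab <- table(x$subjects$diagnosis, useNA = "ifany")
    cat("  diagnosis:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of subjects / variants
#' @param g a genotype_matrix
#' @export
n_subjects <- function(g) nrow(g$subjects)

#' @rdname n_subjects
#' @export
n_variants <- function(g) nrow(g$variants)

#' Read PLINK-style PED/MAP text genotypes
#'
#' The PED file is whitespace-delimited with six leading columns
#' (family, individual, father, mother, sex, phenotype) followed by two
#' allele columns per variant; "0" denotes a missing allele. The MAP file
#' has one row per variant: chromosome, snp id, optional genetic distance,
#' and 1-based bp position. Variants are sorted by (chromosome, position)
#' on load. Phenotype 1 maps to control, 2 to case, anything else to NA.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [genotype_matrix()] carrying raw allele pairs (no dosage yet);
#'   pass it to [recode_minor_allele()] to obtain minor-allele dosages.
#' @export
read_ped_map <- function(ped_path, map_path) {
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(map) == 3L) {
    names(map) <- c("chromosome", "snp_id", "position")
  } else if (ncol(map) >= 4L) {
    map <- map[, 1:4]
    names(map) <- c("chromosome", "snp_id", "cm", "position")
  } else stop("MAP file must have 3 or 4 columns")
  map$position <- as.integer(map$position)
  if (anyNA(map$position) || any(map$position < 1))
    stop("MAP positions must be positive 1-based integers")
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in MAP file")
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("PED file is empty")
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  ids <- character(n); sex <- integer(n); pheno <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop(sprintf(
        "PED line %d has %d fields; expected %d (6 + 2 alleles for each of %d MAP variants)",
        i, length(f), 6L + 2L * m, m))
    ids[i] <- f[2]
    sex[i] <- suppressWarnings(as.integer(f[5]))
    pheno[i] <- f[6]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, by = 2L)]
  }
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing genotype (one allele \"0\") at PED line ",
         which(rowSums(half) > 0)[1])
  for (j in seq_len(m)) {
    obs <- unique(c(a1[, j], a2[, j]))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2L)
      stop("more than 2 alleles observed at variant ", map$snp_id[j], ": ",
           paste(sort(obs), collapse = "/"))
  }
  if (anyDuplicated(ids)) stop("duplicate individual id in PED file")
  diagnosis <- factor(ifelse(pheno == "2", "case",
                             ifelse(pheno == "1", "control", NA)),
                      levels = c("control", "case"))
  subjects <- data.frame(subject_id = ids,
                         diagnosis = diagnosis,
                         sex = factor(ifelse(sex == 1L, "male",
                                             ifelse(sex == 2L, "female", NA)),
                                      levels = c("male", "female")),
                         stringsAsFactors = FALSE)
  variants <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                         position = map$position, stringsAsFactors = FALSE)
  genotype_matrix(NULL, variants, subjects, alleles = list(a1 = a1, a2 = a2))
}

#' Recode raw allele pairs to minor-allele dosage
#'
#' For each variant, the minor allele is the less frequent allele among
#' non-missing alleles in the reference group (default: all subjects;
#' "controls" restricts the frequency count to diagnosed controls, which
#' keeps labels comparable with control-only references). An exact 50/50
#' tie is broken in favour of the lexicographically smaller allele symbol.
#' Dosage is then the per-subject count of the minor allele. Monomorphic
#' variants get maf 0, dosage 0 where called, and minor_allele equal to
#' the unobserved member of the allele pair (NA when only one allele was
#' ever seen) with `monomorphic = TRUE`.
#'
#' Idempotent: recoding an already-recoded matrix recomputes the same
#' dosages from the stored allele pairs.
#'
#' @param g genotype_matrix with raw alleles (from [read_ped_map()]).
#' @param reference_group "all" or "controls".
#' @return genotype_matrix with dosage filled and variant metadata
#'   (minor_allele, maf, call_rate, monomorphic) populated. The reported
#'   maf is always computed over all subjects.
#' @export
recode_minor_allele <- function(g, reference_group = c("all", "controls")) {
  reference_group <- match.arg(reference_group)
  if (is.null(g$alleles)) stop("raw allele pairs are not available")
  a1 <- g$alleles$a1; a2 <- g$alleles$a2
  n <- nrow(a1); m <- ncol(a1)
  ref_rows <- seq_len(n)
  if (reference_group == "controls") {
    if (is.null(g$subjects$diagnosis) || !any(g$subjects$diagnosis == "control", na.rm = TRUE))
      stop("reference_group = \"controls\" requires subjects diagnosed control")
    ref_rows <- which(g$subjects$diagnosis == "control")
  }
  dosage <- matrix(NA_integer_, n, m)
  minor <- character(m); all_a <- character(m); all_b <- character(m)
  maf <- numeric(m); call_rate <- numeric(m); mono <- logical(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- sort(unique(al[!is.na(al)]))
    ref_al <- c(a1[ref_rows, j], a2[ref_rows, j])
    ref_al <- ref_al[!is.na(ref_al)]
    if (length(obs) == 0L) {
      minor[j] <- NA_character_; all_a[j] <- NA_character_; all_b[j] <- NA_character_
      maf[j] <- 0; call_rate[j] <- 0; mono[j] <- TRUE
      next
    }
    if (length(obs) == 1L) {
      all_a[j] <- obs; all_b[j] <- NA_character_
      minor[j] <- NA_character_          # absent partner allele unknown from PED
      mono[j] <- TRUE
      dosage[, j] <- ifelse(is.na(a1[, j]), NA_integer_, 0L)
      maf[j] <- 0
    } else {
      all_a[j] <- obs[1]; all_b[j] <- obs[2]
      cnt <- c(sum(ref_al == obs[1]), sum(ref_al == obs[2]))
      # tie -> lexicographically first symbol (obs is sorted)
      minor[j] <- if (cnt[2] < cnt[1]) obs[2] else obs[1]
      dosage[, j] <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
      allc <- c(a1[, j], a2[, j]); allc <- allc[!is.na(allc)]
      maf[j] <- mean(allc == minor[j])
      mono[j] <- FALSE
    }
    call_rate[j] <- mean(!is.na(a1[, j]))
  }
  v <- g$variants
  v$allele_a <- all_a; v$allele_b <- all_b
  v$minor_allele <- minor; v$maf <- maf; v$call_rate <- call_rate
  v$monomorphic <- mono
  genotype_matrix(dosage, v, g$subjects, alleles = g$alleles)
}

#' Write a genotype matrix back to PED/MAP text
#'
#' Raw allele pairs are used when present; otherwise dosages are written
#' with the minor/major allele symbols from the variant table.
#' @param g genotype_matrix
#' @param ped_path,map_path output paths
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  v <- g$variants
  utils::write.table(
    data.frame(v$chromosome, v$snp_id, 0, v$position),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- n_subjects(g); m <- n_variants(g)
  if (!is.null(g$alleles)) {
    a1 <- g$alleles$a1; a2 <- g$alleles$a2
  } else {
    if (is.null(g$dosage)) stop("no alleles and no dosage to write")
    minor <- v$minor_allele
    major <- ifelse(v$allele_a == minor | is.na(minor), v$allele_b, v$allele_a)
    major[is.na(major)] <- v$allele_a[is.na(major)]
    a1 <- matrix(NA_character_, n, m); a2 <- a1
    for (j in seq_len(m)) {
      d <- g$dosage[, j]
      a1[, j] <- ifelse(is.na(d), NA, ifelse(d >= 1, minor[j], major[j]))
      a2[, j] <- ifelse(is.na(d), NA, ifelse(d == 2, minor[j], major[j]))
    }
  }
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  sexcode <- ifelse(is.na(g$subjects$sex), 0L,
                    ifelse(g$subjects$sex == "male", 1L, 2L))
  phcode <- if (is.null(g$subjects$diagnosis)) rep(0L, n) else
    ifelse(is.na(g$subjects$diagnosis), 0L,
           ifelse(g$subjects$diagnosis == "case", 2L, 1L))
  inter <- matrix(NA_character_, n, 2L * m)
  inter[, seq(1L, 2L * m, by = 2L)] <- a1
  inter[, seq(2L, 2L * m, by = 2L)] <- a2
  rows <- cbind(g$subjects$subject_id, g$subjects$subject_id, 0, 0,
                sexcode, phcode, inter)
  writeLines(apply(rows, 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a subject covariate table
#'
#' Tab-separated with header. Required columns: subject_id, diagnosis
#' (case/control or 2/1), age, sex (male/female or 1/2), apoe4_dosage
#' (0/1/2), series. Optional: cohort. Strict validation: duplicate
#' subject ids, missing required columns and out-of-domain apoe4_dosage
#' are errors.
#'
#' @param path TSV path
#' @return data.frame of typed subject records
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("subject_id", "diagnosis", "age", "sex", "apoe4_dosage", "series")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$subject_id))
    stop("duplicate subject_id: ", d$subject_id[duplicated(d$subject_id)][1])
  d$subject_id <- as.character(d$subject_id)
  dg <- as.character(d$diagnosis)
  dg[dg == "1"] <- "control"; dg[dg == "2"] <- "case"
  if (!all(dg %in% c("case", "control", NA)))
    stop("diagnosis must be case/control (or 2/1)")
  d$diagnosis <- factor(dg, levels = c("control", "case"))
  sx <- as.character(d$sex)
  sx[sx == "1"] <- "male"; sx[sx == "2"] <- "female"
  if (!all(sx %in% c("male", "female", NA)))
    stop("sex must be male/female (or 1/2)")
  d$sex <- factor(sx, levels = c("male", "female"))
  d$age <- as.numeric(d$age)
  a4 <- suppressWarnings(as.integer(d$apoe4_dosage))
  if (any(!is.na(d$apoe4_dosage) & (is.na(a4) | !(a4 %in% 0:2))))
    stop("apoe4_dosage must be 0, 1 or 2")
  d$apoe4_dosage <- a4
  d$series <- as.character(d$series)
  if (any(!nzchar(d$series) | is.na(d$series))) stop("series labels must be non-empty")
  d
}

#' Write a subject covariate table (round-trips with [read_covariates()])
#' @param subjects data.frame of subject records
#' @param path output TSV path
#' @export
write_covariates <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a labeled numeric TSV (first column = row key)
#' @param path TSV path with header
#' @return numeric matrix with rownames from the first column
#' @export
read_numeric_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(d[[1]])) stop("duplicate row keys in ", path)
  keys <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in table ", path)
  rownames(m) <- keys
  m
}
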