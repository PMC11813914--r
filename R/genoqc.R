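#' Construct a genotype matrix object
#'
#' @param calls Animals x SNPs numeric matrix of A1-allele doses in
#'   {0,1,2}, NA for missing. Row names are animal ids, column names SNP
#'   ids (filled in if absent).
#' @param map Data frame with one row per SNP: `snp_id`, `chrom`,
#'   `pos_bp` (1-based), and optionally `a1`, `a2`.
#' @return List of class `genotype_matrix` with elements `calls`, `map`.
#' @export
genotype_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("animal_%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- map$snp_id
  if (ncol(calls) != nrow(map))
    stop("genotype_matrix: calls has ", ncol(calls),
         " SNPs but map has ", nrow(map), call. = FALSE)
  if (!all(c("snp_id", "chrom", "pos_bp") %in% names(map)))
    stop("genotype_matrix: map needs columns snp_id, chrom, pos_bp",
         call. = FALSE)
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  map$chrom <- as.character(map$chrom)
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("genotype_matrix: calls must lie in [0, 2]", call. = FALSE)
  rownames(map) <- NULL
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "animals x", ncol(x$calls),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s);",
      sum(is.na(x$calls)), "missing call(s)\n")
  invisible(x)
}

#' A1 allele frequencies of a genotype matrix
#'
#' @param geno A `genotype_matrix` or plain dose matrix.
#' @return Numeric vector of per-SNP A1 frequencies (missing calls skipped).
#' @export
allele_freq <- function(geno) {
  calls <- if (inherits(geno, "genotype_matrix")) geno$calls else geno
  colMeans(calls, na.rm = TRUE) / 2
}

# exact HWE p-value with a shared tie tolerance so that independently
# coded enumerations agree bit-for-tie; tol is relative on probability mass
hwe_tie_tol <- 1e-9

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (standard GWAS-QC formulation; no mid-p correction).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)))
    stop("hwe_exact_test: SNP has no called genotypes", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("hwe_exact_test: counts must be non-negative integers",
         call. = FALSE)
  n <- sum(counts)
  if (n < 1)
    stop("hwe_exact_test: SNP has no called genotypes", call. = FALSE)
  n1 <- 2 * n_AA + n_Aa          # copies of the first allele
  minor <- min(n1, 2 * n - n1)   # conditioning is symmetric in the alleles
  hets <- seq(minor %% 2, minor, by = 2)
  # log P(h | n, minor) up to the normalizing constant
  homr <- (minor - hets) / 2
  homc <- n - hets - homr
  logp <- lgamma(n + 1) - lgamma(homr + 1) - lgamma(hets + 1) -
    lgamma(homc + 1) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- min(n_Aa, minor)  # observed het count on the minor-allele scale
  p_obs <- pr[match(obs, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + hwe_tie_tol)]))
}

#' Apply the study's SNP and sample quality-control filters
#'
#' Filters are applied in a fixed, documented order (counts depend on it):
#' 1. SNPs with unknown chromosome/position or sharing a (chrom, pos) with
#'    another SNP are removed;
#' 2. animals with call rate below `animal_callrate_min`;
#' 3. SNPs with call rate below `snp_callrate_min`;
#' 4. SNPs with minor allele frequency `<= maf_max_excl` (inclusive);
#' 5. SNPs with exact HWE p-value `< hwe_p`.
#' Surviving missing calls are mean-imputed to twice the allele frequency
#' so downstream matrix algebra sees complete doses.
#'
#' @param geno A `genotype_matrix`.
#' @param hwe_p HWE exclusion threshold (default 1e-6).
#' @param maf_max_excl MAF at or below which a SNP is removed (default 0.01).
#' @param snp_callrate_min Minimum SNP call rate (default 0.99).
#' @param animal_callrate_min Minimum per-animal call rate (default 0.90).
#' @return List with `geno` (filtered, imputed `genotype_matrix`) and
#'   `report` (class `qc_report`): input/removed/passing counts per rule
#'   plus the thresholds used.
#' @export
apply_qc <- function(geno, hwe_p = 1e-6, maf_max_excl = 0.01,
                     snp_callrate_min = 0.99, animal_callrate_min = 0.90) {
  stopifnot(inherits(geno, "genotype_matrix"))
  calls <- geno$calls
  map <- geno$map
  if (ncol(calls) == 0L)
    stop("apply_qc: empty genotype matrix", call. = FALSE)
  n_input <- ncol(calls)

  # 1. unmapped or duplicate-position SNPs (all members of a duplicate
  #    (chrom, pos) group are dropped)
  unmapped <- is.na(map$chrom) | map$chrom %in% c("", "0", "NA") |
    is.na(map$pos_bp) | map$pos_bp < 1
  key <- paste(map$chrom, map$pos_bp)
  dup <- key %in% key[duplicated(key)] & !unmapped
  drop1 <- unmapped | dup
  calls <- calls[, !drop1, drop = FALSE]
  map <- map[!drop1, , drop = FALSE]

  # 2. animal call rate
  acr <- rowMeans(!is.na(calls))
  bad_animal <- acr < animal_callrate_min
  calls <- calls[!bad_animal, , drop = FALSE]

  # 3. SNP call rate
  scr <- colMeans(!is.na(calls))
  drop3 <- scr < snp_callrate_min
  calls <- calls[, !drop3, drop = FALSE]
  map <- map[!drop3, , drop = FALSE]

  # 4. MAF (inclusive threshold)
  p <- allele_freq(calls)
  maf <- pmin(p, 1 - p)
  drop4 <- maf <= maf_max_excl
  calls <- calls[, !drop4, drop = FALSE]
  map <- map[!drop4, , drop = FALSE]

  # 5. exact HWE
  drop5 <- logical(ncol(calls))
  if (ncol(calls)) {
    for (j in seq_len(ncol(calls))) {
      cj <- calls[, j]
      cj <- cj[!is.na(cj)]
      pval <- hwe_exact_test(sum(cj == 2), sum(cj == 1), sum(cj == 0))
      drop5[j] <- pval < hwe_p
    }
  }
  calls <- calls[, !drop5, drop = FALSE]
  map <- map[!drop5, , drop = FALSE]

  if (ncol(calls) == 0L)
    stop("apply_qc: all SNPs removed by quality control", call. = FALSE)

  # mean imputation to 2p for surviving missing calls
  if (anyNA(calls)) {
    mu <- colMeans(calls, na.rm = TRUE)
    nas <- which(is.na(calls), arr.ind = TRUE)
    calls[nas] <- mu[nas[, 2]]
  }

  report <- structure(list(
    n_input_snps = n_input,
    n_removed_unmapped_or_dup = sum(drop1),
    n_removed_animals = sum(bad_animal),
    n_removed_snp_callrate = sum(drop3),
    n_removed_maf = sum(drop4),
    n_removed_hwe = sum(drop5),
    n_pass = ncol(calls),
    thresholds = list(hwe_p = hwe_p, maf_max_excl = maf_max_excl,
                      snp_callrate_min = snp_callrate_min,
                      animal_callrate_min = animal_callrate_min)
  ), class = "qc_report")
  list(geno = genotype_matrix(calls, map), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control:\n",
      " input SNPs           ", x$n_input_snps, "\n",
      " unmapped/duplicate   ", x$n_removed_unmapped_or_dup, "\n",
      " animals removed      ", x$n_removed_animals, "\n",
      " SNP call rate        ", x$n_removed_snp_callrate, "\n",
      " MAF                  ", x$n_removed_maf, "\n",
      " HWE                  ", x$n_removed_hwe, "\n",
      " passing              ", x$n_pass, "\n")
  invisible(x)
}

#' Write a genotype matrix as PED/MAP text
#'
#' PED columns: FID IID PAT MAT SEX PHENO then two allele columns per SNP
#' ("0 0" for missing), whitespace-separated. MAP columns: chrom, snp_id,
#' cM (0), pos_bp.
#'
#' @param geno A `genotype_matrix`.
#' @param prefix Output path prefix; writes `<prefix>.ped`, `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_ped <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  calls <- geno$calls
  map <- geno$map
  n <- nrow(calls); m <- ncol(calls)
  a1 <- matrix(rep(map$a1, each = n), n, m)
  a2 <- matrix(rep(map$a2, each = n), n, m)
  al1 <- ifelse(is.na(calls), "0", ifelse(calls >= 1, a1, a2))
  al2 <- ifelse(is.na(calls), "0", ifelse(calls == 2, a1, a2))
  geno_cols <- matrix("", n, 2 * m)
  geno_cols[, seq(1, 2 * m, 2)] <- al1
  geno_cols[, seq(2, 2 * m, 2)] <- al2
  ped <- cbind("FAM1", rownames(calls), "0", "0", "0", "-9", geno_cols)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mp <- data.frame(map$chrom, map$snp_id, 0, map$pos_bp)
  utils::write.table(mp, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read a PED/MAP pair into a genotype matrix
#'
#' Doses count copies of the MAP `a1` allele when allele columns are
#' provided; otherwise A1 is the first allele observed at each marker.
#' Rounded genotypes written by [write_ped()] round-trip exactly.
#'
#' @param prefix Path prefix of `<prefix>.ped` and `<prefix>.map`.
#' @return A `genotype_matrix`.
#' @export
read_ped <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "snp_id", "cm", "pos_bp")
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("read_ped: PED has ", ncol(ped) - 6,
         " allele columns but MAP lists ", m, " SNPs", call. = FALSE)
  ids <- ped[[2]]
  calls <- matrix(NA_integer_, nrow(ped), m,
                  dimnames = list(ids, map$snp_id))
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- ped[[6 + 2 * j - 1]]
    x2 <- ped[[6 + 2 * j]]
    miss <- x1 == "0" | x2 == "0"
    obs <- unique(c(x1[!miss], x2[!miss]))
    a1[j] <- if (length(obs) >= 1) obs[1] else "A"
    a2[j] <- if (length(obs) >= 2) obs[2] else "B"
    calls[, j] <- (x1 == a1[j]) + (x2 == a1[j])
    calls[miss, j] <- NA_integer_
  }
  genotype_matrix(calls, data.frame(snp_id = map$snp_id, chrom = map$chrom,
                                    pos_bp = map$pos_bp, a1 = a1, a2 = a2,
                                    stringsAsFactors = FALSE))
}

#' Read a simple calls TSV into a genotype matrix
#'
#' Expects a TSV whose first column is the animal id and remaining columns
#' are per-SNP doses in {0,1,2} (NA allowed), plus a companion map TSV
#' with columns snp_id, chrom, pos_bp.
#'
#' @param calls_path,map_path File paths.
#' @return A `genotype_matrix`.
#' @export
read_calls_tsv <- function(calls_path, map_path) {
  tab <- utils::read.table(calls_path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           colClasses = c(snp_id = "character",
                                          chrom = "character"))
  calls <- as.matrix(tab[, -1, drop = FALSE])
  rownames(calls) <- tab[[1]]
  genotype_matrix(calls, map)
}
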