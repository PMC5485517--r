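#' Construct a case-control genotype dataset
#'
#' Bundles an N x M matrix of genotype codes (0/1/2 = copies of the minor
#' allele, `NA` = missing) with a binary phenotype (1 = case, 0 = control).
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns.
#' @param phenotype vector of 0/1 disease status, length `nrow(genotypes)`.
#' @param snp_ids unique SNP identifiers (default from column names).
#' @param sample_ids sample identifiers (default from row names).
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `phenotype`, `snp_ids`, `sample_ids`, `n_case`, `n_control`.
#' @export
genotype_dataset <- function(genotypes, phenotype, snp_ids = NULL,
                             sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length must equal the number of genotype rows")
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be coded 0 (control) / 1 (case)")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (length(snp_ids) != ncol(genotypes))
    stop("snp_ids length must equal the number of SNPs")
  if (is.null(sample_ids)) sample_ids <- rownames(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(genotypes)))
  dimnames(genotypes) <- NULL
  structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_ids = snp_ids, sample_ids = as.character(sample_ids),
         n_case = sum(phenotype == 1L), n_control = sum(phenotype == 0L)),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Case-control genotype dataset\n")
  cat(sprintf("  %d samples (%d cases, %d controls), %d SNPs\n",
              nrow(x$genotypes), x$n_case, x$n_control, ncol(x$genotypes)))
  nmiss <- sum(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$genotypes)))
  invisible(x)
}

#' Read case-control genotype data
#'
#' Supports two plain-text dialects:
#' \describe{
#'   \item{`tsv`}{Tab-separated; header row with `sample_id`, `phenotype` and
#'     then one column per SNP id; phenotype in `{0,1}`; genotype cells in
#'     `{0,1,2,NA}` (minor-allele counts).}
#'   \item{`pedmap`}{PLINK text format: `<prefix>.ped` (FID IID PID MID SEX
#'     PHENO then two allele columns per SNP, allele `0` = missing) and
#'     `<prefix>.map` (chromosome, SNP id, \[genetic distance,\] position).
#'     Phenotype 1/2 is mapped to 0/1 (2 = case); 0/1 phenotypes are kept.
#'     Genotypes are recoded as counts of the minor allele, the minor allele
#'     being the less frequent allele over all samples (ties broken towards
#'     the lexicographically larger allele).}
#' }
#'
#' @param path file path; for `pedmap` either the `.ped` file or the common
#'   prefix of the `.ped`/`.map` pair.
#' @param format `"tsv"` or `"pedmap"`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("tsv", "pedmap")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_pedmap(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("genotype TSV needs a header and >= 1 sample")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L)
    stop("genotype TSV header must have sample_id, phenotype and >= 1 SNP")
  snp_ids <- header[-(1:2)]
  n <- length(lines) - 1L
  geno <- matrix(NA_integer_, n, length(snp_ids))
  pheno <- integer(n)
  sid <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header))
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   i + 1L, length(header), length(f)))
    sid[i] <- f[1L]
    pheno[i] <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pheno[i]) || !pheno[i] %in% c(0L, 1L))
      stop(sprintf("parse error at line %d: phenotype must be 0 or 1", i + 1L))
    g <- f[-(1:2)]
    g[g %in% c("NA", "")] <- NA
    gi <- suppressWarnings(as.integer(g))
    if (any(!is.na(g) & (is.na(gi) | !gi %in% 0:2)))
      stop(sprintf("parse error at line %d: genotypes must be 0/1/2/NA",
                   i + 1L))
    geno[i, ] <- gi
  }
  genotype_dataset(geno, pheno, snp_ids = snp_ids, sample_ids = sid)
}

read_genotypes_pedmap <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped <- paste0(prefix, ".ped")
  map <- paste0(prefix, ".map")
  if (!file.exists(ped)) stop("file not found: ", ped)
  if (!file.exists(map)) stop("file not found: ", map)
  map_df <- read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(map_df) %in% c(3L, 4L))
    stop(".map must have 3 or 4 columns")
  snp_ids <- as.character(map_df[[2L]])
  M <- length(snp_ids)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n < 1L) stop(".ped contains no samples")
  a1 <- matrix("", n, M)
  a2 <- matrix("", n, M)
  pheno_raw <- integer(n)
  sid <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 6L + 2L * M)
      stop(sprintf("parse error at line %d of .ped: expected %d fields, got %d",
                   i, 6L + 2L * M, length(f)))
    sid[i] <- f[2L]
    pheno_raw[i] <- suppressWarnings(as.integer(f[6L]))
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1L, by = 2L, length.out = M)]
    a2[i, ] <- al[seq(2L, by = 2L, length.out = M)]
  }
  if (all(pheno_raw %in% c(1L, 2L))) {
    pheno <- pheno_raw - 1L
  } else if (all(pheno_raw %in% c(0L, 1L))) {
    pheno <- pheno_raw
  } else {
    stop("unsupported .ped phenotype coding (expect 1/2 or 0/1)")
  }
  geno <- matrix(NA_integer_, n, M)
  for (j in seq_len(M)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("non-biallelic SNP rejected: ", snp_ids[j])
    if (length(alleles) == 0L) next  # fully missing SNP
    if (length(alleles) == 1L) {
      minor <- NA_character_  # monomorphic: zero minor-allele copies
    } else {
      cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
      # minor = less frequent; tie -> lexicographically larger allele
      minor <- if (cnt[1L] < cnt[2L]) alleles[1L]
               else if (cnt[2L] < cnt[1L]) alleles[2L]
               else alleles[2L]
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    g <- if (is.na(minor)) integer(n)
         else (a1[, j] == minor) + (a2[, j] == minor)
    g[miss] <- NA_integer_
    geno[, j] <- as.integer(g)
  }
  genotype_dataset(geno, pheno, snp_ids = snp_ids, sample_ids = sid)
}

#' Write a genotype dataset in the TSV dialect
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  header <- paste(c("sample_id", "phenotype", ds$snp_ids), collapse = "\t")
  g <- ds$genotypes
  body <- vapply(seq_len(nrow(g)), function(i) {
    paste(c(ds$sample_ids[i], ds$phenotype[i],
            ifelse(is.na(g[i, ]), "NA", g[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Hardy-Weinberg equilibrium goodness-of-fit p-value
#'
#' One-degree-of-freedom chi-squared goodness of fit of observed genotype
#' counts `(n0, n1, n2)` against Hardy-Weinberg expectations at the sample
#' allele frequency. Monomorphic input (allele frequency 0 or 1) returns
#' `p = 1` by convention.
#'
#' @param counts non-negative integer vector of length 3 (counts of genotype
#'   codes 0, 1, 2).
#' @return The upper-tail p-value.
#' @export
hwe_pvalue <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  p <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((counts - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Quality-control thresholds
#'
#' @param snp_call_rate_min minimum per-SNP call rate across all samples.
#' @param sample_call_rate_min minimum per-sample call rate.
#' @param hwe_p_min minimum Hardy-Weinberg p-value in controls.
#' @param maf_min minimum minor allele frequency.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.95,
                          sample_call_rate_min = 0.98,
                          hwe_p_min = 1e-4,
                          maf_min = 0.1) {
  v <- c(snp_call_rate_min, sample_call_rate_min, hwe_p_min, maf_min)
  if (any(v <= 0) || any(v >= 1))
    stop("all QC thresholds must lie in (0, 1)")
  structure(list(snp_call_rate_min = snp_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min,
                 hwe_p_min = hwe_p_min, maf_min = maf_min),
            class = "qc_thresholds")
}

#' Quality control of a genotype dataset
#'
#' Filters are applied in a fixed order, each on the data surviving the
#' previous step: (1) samples with call rate below
#' `sample_call_rate_min`; (2) SNPs with call rate below `snp_call_rate_min`;
#' (3) SNPs failing Hardy-Weinberg equilibrium in controls
#' (`hwe_pvalue() < hwe_p_min`); (4) SNPs with minor allele frequency below
#' `maf_min` (frequency folded to `min(f, 1 - f)` over all samples).
#'
#' @param ds a [genotype_dataset()].
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with elements `dataset` (the filtered [genotype_dataset()])
#'   and `report` (a data frame with columns `entity_type`, `entity`, `rule`,
#'   `value`, `threshold`, one row per removed sample/SNP).
#' @export
quality_control <- function(ds, thresholds = qc_thresholds()) {
  stopifnot(inherits(ds, "genotype_dataset"),
            inherits(thresholds, "qc_thresholds"))
  report <- data.frame(entity_type = character(), entity = character(),
                       rule = character(), value = numeric(),
                       threshold = numeric(), stringsAsFactors = FALSE)
  g <- ds$genotypes
  pheno <- ds$phenotype
  sids <- ds$sample_ids
  snps <- ds$snp_ids

  add <- function(type, entity, rule, value, thr) {
    rbind(report, data.frame(entity_type = type, entity = entity, rule = rule,
                             value = value, threshold = thr,
                             stringsAsFactors = FALSE))
  }

  # 1. sample call rate (over all current SNPs)
  cr_s <- rowMeans(!is.na(g))
  drop_s <- which(cr_s < thresholds$sample_call_rate_min)
  for (i in drop_s)
    report <- add("sample", sids[i], "sample_call_rate", cr_s[i],
                  thresholds$sample_call_rate_min)
  if (length(drop_s)) {
    g <- g[-drop_s, , drop = FALSE]
    pheno <- pheno[-drop_s]
    sids <- sids[-drop_s]
  }
  if (nrow(g) == 0L) stop("quality control removed all samples")

  # 2. SNP call rate
  cr_m <- colMeans(!is.na(g))
  drop_m <- which(cr_m < thresholds$snp_call_rate_min)
  for (j in drop_m)
    report <- add("snp", snps[j], "snp_call_rate", cr_m[j],
                  thresholds$snp_call_rate_min)
  if (length(drop_m)) {
    g <- g[, -drop_m, drop = FALSE]
    snps <- snps[-drop_m]
  }

  # 3. HWE in controls
  if (ncol(g)) {
    ctrl <- g[pheno == 0L, , drop = FALSE]
    hwe <- vapply(seq_len(ncol(g)), function(j) {
      cnt <- tabulate(ctrl[, j] + 1L, 3L)
      if (sum(cnt) < 1L) return(1)
      hwe_pvalue(cnt)
    }, numeric(1))
    drop_h <- which(hwe < thresholds$hwe_p_min)
    for (j in drop_h)
      report <- add("snp", snps[j], "hwe_controls", hwe[j],
                    thresholds$hwe_p_min)
    if (length(drop_h)) {
      g <- g[, -drop_h, drop = FALSE]
      snps <- snps[-drop_h]
    }
  }

  # 4. MAF over all samples, folded
  if (ncol(g)) {
    f <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    maf[is.nan(maf)] <- 0
    drop_f <- which(maf < thresholds$maf_min)
    for (j in drop_f)
      report <- add("snp", snps[j], "maf", maf[j], thresholds$maf_min)
    if (length(drop_f)) {
      g <- g[, -drop_f, drop = FALSE]
      snps <- snps[-drop_f]
    }
  }

  if (ncol(g) == 0L) stop("quality control removed all SNPs")
  list(dataset = genotype_dataset(g, pheno, snp_ids = snps,
                                  sample_ids = sids),
       report = report)
}

#' Write a QC removal report as TSV
#'
#' @param report the `report` element returned by [quality_control()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
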