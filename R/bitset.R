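#' Bit-encode a genotype dataset
#'
#' For every SNP, three bitsets (one per genotype code) are stored per
#' phenotype class; bit `s` of the genotype-`g` bitset is set iff sample `s`
#' of that class carries genotype `g`. Missing genotypes are 0 in all three
#' bitsets of their class. Contingency tables for any k-SNP combination are
#' then popcounts of bitwise ANDs ([contingency_table()]).
#'
#' @param ds a [genotype_dataset()].
#' @return An object of class `bit_dataset`: a list with raw arrays `case`
#'   and `control` of dim `(nbytes, 3, M)` (bitsets padded to 64-bit words),
#'   the class sizes `n_case`/`n_control`, the SNP count `M` and `snp_ids`.
#' @export
bit_encode <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  M <- ncol(ds$genotypes)
  pack_class <- function(cls) {
    sub <- ds$genotypes[ds$phenotype == cls, , drop = FALSE]
    n <- nrow(sub)
    nbits <- 64L * max(1L, as.integer(ceiling(n / 64)))
    nbytes <- nbits %/% 8L
    arr <- array(as.raw(0L), dim = c(nbytes, 3L, M))
    pad <- matrix(FALSE, nbits, M)
    for (g in 0:2) {
      pad[] <- FALSE
      if (n > 0L)
        pad[seq_len(n), ] <- !is.na(sub) & sub == g
      arr[, g + 1L, ] <- array(packBits(as.logical(pad), type = "raw"),
                               dim = c(nbytes, M))
    }
    arr
  }
  structure(list(case = pack_class(1L), control = pack_class(0L),
                 n_case = ds$n_case, n_control = ds$n_control,
                 M = M, snp_ids = ds$snp_ids),
            class = "bit_dataset")
}

#' @export
print.bit_dataset <- function(x, ...) {
  cat(sprintf("Bit-encoded dataset: %d SNPs, %d cases, %d controls\n",
              x$M, x$n_case, x$n_control))
  invisible(x)
}

#' k-locus contingency table by bitwise counting
#'
#' Builds the `3^k x 2` genotype-combination by case/control table for an
#' ordered tuple of SNPs. Rows are ordered lexicographically over
#' `(g1, ..., gk)` with the first SNP varying slowest. Samples missing at any
#' of the k SNPs are excluded from the table.
#'
#' @param bits a [bit_encode()]d dataset.
#' @param snps ordered vector of distinct 1-based SNP indices (k >= 1).
#' @return An object of class `contingency_table`: a list with `counts`
#'   (integer matrix, columns `case`, `control`), `row_margins`,
#'   `col_margins`, `N`, `k` and `snps`.
#' @export
contingency_table <- function(bits, snps) {
  stopifnot(inherits(bits, "bit_dataset"))
  snps <- as.integer(snps)
  if (length(snps) < 1L) stop("need at least one SNP index")
  if (anyDuplicated(snps)) stop("duplicate SNP indices")
  if (any(snps < 1L | snps > bits$M)) stop("SNP index out of range")
  counts <- cpp_contingency(bits$case, bits$control, snps)
  colnames(counts) <- c("case", "control")
  k <- length(snps)
  rownames(counts) <- vapply(0:(3L^k - 1L), function(u) {
    g <- integer(k)
    for (i in k:1) { g[i] <- u %% 3L; u <- u %/% 3L }
    paste(g, collapse = "/")
  }, character(1))
  structure(list(counts = counts,
                 row_margins = rowSums(counts),
                 col_margins = colSums(counts),
                 N = sum(counts), k = k, snps = snps),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("%d-locus contingency table (%d x 2), N = %d\n",
              x$k, nrow(x$counts), x$N))
  print(x$counts)
  invisible(x)
}

# Per-SNP 3 x 2 genotype-by-class counts for all SNPs (3 x M per class).
single_locus_counts <- function(bits) {
  list(case = cpp_genotype_counts(bits$case),
       control = cpp_genotype_counts(bits$control))
}
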