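#' Pairwise chi-squared scan over all SNP pairs
#'
#' Tests all `choose(M, 2)` pairs ([chi_squared_test()], df = 8) and retains
#' those with statistic above the intermediate critical value
#' `chi2_alpha_prime`; each retained pair is labelled `"significant"`
#' (statistic above `chi2_alpha`) or `"intermediate"`. Non-retained pairs
#' (the no/little-association group) are never materialized.
#'
#' @param bits a [bit_encode()]d dataset.
#' @param scheme a [significance_scheme()].
#' @return A data frame of class `pair_groups` with columns `snp_a`, `snp_b`
#'   (1-based indices, `snp_a < snp_b`), `chi2`, `df`, `p`, `band`, ordered
#'   by descending statistic (ties by index order). The scheme and the count
#'   `W` of retained pairs are attached as attributes `scheme` and `W`.
#' @export
pairwise_scan <- function(bits, scheme) {
  stopifnot(inherits(bits, "bit_dataset"),
            inherits(scheme, "significance_scheme"))
  if (bits$M < 2L) stop("need at least two SNPs")
  m <- cpp_pair_scan(bits$case, bits$control, scheme$chi2_alpha_prime)
  if (nrow(m) == 0L) {
    out <- data.frame(snp_a = integer(0), snp_b = integer(0),
                      chi2 = numeric(0), df = integer(0), p = numeric(0),
                      band = character(0), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(snp_a = as.integer(m[, 1L]),
                      snp_b = as.integer(m[, 2L]),
                      chi2 = m[, 3L], df = 8L,
                      p = pchisq(m[, 3L], df = 8, lower.tail = FALSE),
                      stringsAsFactors = FALSE)
    out$band <- ifelse(out$chi2 > scheme$chi2_alpha, "significant",
                       "intermediate")
    ord <- order(-out$chi2, out$snp_a, out$snp_b)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "scheme") <- scheme
  attr(out, "W") <- nrow(out)
  class(out) <- c("pair_groups", "data.frame")
  out
}

#' Flag SNPs with a strong main effect
#'
#' A SNP is flagged when its single-locus chi-squared test (3 x 2 genotype by
#' case/control table, df = 2) has p-value below the Bonferroni-corrected
#' level `alpha0 / M`.
#'
#' @param bits a [bit_encode()]d dataset.
#' @param alpha0 preset significance level (default 0.05).
#' @return Integer vector of flagged SNP indices.
#' @export
flag_strong_main_effects <- function(bits, alpha0 = 0.05) {
  stopifnot(inherits(bits, "bit_dataset"))
  cnt <- single_locus_counts(bits)
  thr <- alpha0 / bits$M
  p <- vapply(seq_len(bits$M), function(j) {
    tab <- cbind(case = cnt$case[, j], control = cnt$control[, j])
    chi_squared_test(tab)$p_value
  }, numeric(1))
  which(p < thr)
}

#' Stage 1: screen SNP pairs into the candidate set
#'
#' Runs the full screening pipeline: [pairwise_scan()] retains pairs with
#' intermediate or significant association; [flag_strong_main_effects()]
#' identifies SNPs with strong single-locus association; for every retained
#' pair containing at least one flagged SNP, the likelihood-ratio deviance
#' ([lrt_deviance()]) is computed and the pair discarded iff its p-value
#' exceeds `alpha'` (the association is then attributed to main effects).
#' Pairs with no flagged SNP pass through untouched, and when no SNP is
#' flagged at all the likelihood-ratio stage is skipped entirely.
#'
#' @param ds a [genotype_dataset()] (assumed to have passed QC).
#' @param alpha0 preset significance level (default 0.05).
#' @param omega intermediate-band scale factor (default `1e4`).
#' @param bits optional pre-computed [bit_encode()]d dataset.
#' @return A list of class `screen_result` with `candidates` (data frame as
#'   in [pairwise_scan()] plus an `lrt_p` column, `NA` where the test was
#'   skipped), `flagged`, `scheme`, `W` (number of candidates),
#'   `n_significant`, `n_intermediate`, `n_lrt_tested`, `n_lrt_discarded`.
#' @export
screen <- function(ds, alpha0 = 0.05, omega = 1e4, bits = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(bits)) bits <- bit_encode(ds)
  scheme <- significance_scheme(bits$M, alpha0 = alpha0, omega = omega)
  pairs <- pairwise_scan(bits, scheme)
  flagged <- flag_strong_main_effects(bits, alpha0 = alpha0)
  pairs$lrt_p <- rep(NA_real_, nrow(pairs))
  n_tested <- 0L
  discard <- logical(nrow(pairs))
  if (length(flagged) && nrow(pairs)) {
    has_flag_a <- pairs$snp_a %in% flagged
    has_flag_b <- pairs$snp_b %in% flagged
    idx <- which(has_flag_a | has_flag_b)
    n_tested <- length(idx)
    for (r in idx) {
      res <- lrt_deviance(ds, c(pairs$snp_a[r], pairs$snp_b[r]),
                          c(has_flag_a[r], has_flag_b[r]))
      pairs$lrt_p[r] <- res$p_value
      if (res$p_value > scheme$alpha_prime) discard[r] <- TRUE
    }
  }
  candidates <- pairs[!discard, , drop = FALSE]
  rownames(candidates) <- NULL
  structure(list(candidates = candidates, flagged = flagged, scheme = scheme,
                 W = nrow(candidates),
                 n_significant = sum(candidates$band == "significant"),
                 n_intermediate = sum(candidates$band == "intermediate"),
                 n_lrt_tested = n_tested,
                 n_lrt_discarded = sum(discard)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Stage-1 screening result\n")
  print(x$scheme)
  cat(sprintf("  candidates W = %d (%d significant, %d intermediate)\n",
              x$W, x$n_significant, x$n_intermediate))
  cat(sprintf("  strong-main-effect SNPs: %d; LRT tested %d, discarded %d\n",
              length(x$flagged), x$n_lrt_tested, x$n_lrt_discarded))
  invisible(x)
}
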