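# Independent oracles and fixture builders shared across tests.
# Oracles deliberately avoid the package's counting/fitting code paths.

hwe_probs_test <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

# naive k-locus contingency counting by nested comparison (oracle for the
# bitwise popcount path)
naive_contingency <- function(geno, pheno, snps) {
  k <- length(snps)
  nrows <- 3L^k
  out <- matrix(0L, nrows, 2L, dimnames = list(NULL, c("case", "control")))
  sub <- geno[, snps, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  sub <- sub[complete, , drop = FALSE]
  ph <- pheno[complete]
  for (u in seq_len(nrows) - 1L) {
    g <- integer(k)
    v <- u
    for (i in k:1) { g[i] <- v %% 3L; v <- v %/% 3L }
    hit <- rowSums(sub == matrix(g, nrow(sub), k, byrow = TRUE)) == k
    out[u + 1L, 1L] <- sum(hit & ph == 1L)
    out[u + 1L, 2L] <- sum(hit & ph == 0L)
  }
  out
}

# textbook chi-squared of independence via stats::chisq.test on the rows
# with positive margin (independent of the package's Eq.-style summation)
chi2_oracle <- function(counts) {
  keep <- rowSums(counts) > 0
  unname(suppressWarnings(
    stats::chisq.test(counts[keep, , drop = FALSE], correct = FALSE)$statistic))
}

# random complete genotype dataset under the null
random_dataset <- function(n, m, maf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.2, 0.5)
  g <- sapply(seq_len(m), function(j) rbinom(n, 2L, maf[j]))
  genotype_dataset(g, rep(0:1, length.out = n))
}

# dataset with one pure main-effect SNP (column 1): case probability depends
# multiplicatively on its genotype, all other SNPs are noise
main_effect_dataset <- function(n_case, n_ctrl, m, risk = 2, maf = 0.3,
                                base = 0.1) {
  acc_g <- NULL
  acc_y <- integer(0)
  while (sum(acc_y == 1L) < n_case || sum(acc_y == 0L) < n_ctrl) {
    b <- 4L * (n_case + n_ctrl)
    g1 <- rbinom(b, 2L, maf)
    f <- pmin(base * risk^g1, 0.95)
    y <- as.integer(runif(b) < f)
    take_ca <- which(y == 1L)[seq_len(min(n_case - sum(acc_y == 1L),
                                          sum(y == 1L)))]
    take_co <- which(y == 0L)[seq_len(min(n_ctrl - sum(acc_y == 0L),
                                          sum(y == 0L)))]
    take <- c(take_ca, take_co)
    acc_g <- c(acc_g, g1[take])
    acc_y <- c(acc_y, y[take])
  }
  n <- length(acc_y)
  geno <- cbind(acc_g,
                sapply(seq_len(m - 1L), function(j) rbinom(n, 2L, 0.3)))
  colnames(geno) <- NULL
  genotype_dataset(geno, acc_y)
}

# strong purely pairwise interaction model on two loci (for screening and
# pheromone-concentration fixtures)
strong_pair_model <- function(maf = 0.3, f_hi = 0.5, f_lo = 0.05) {
  tab <- matrix(f_lo, 3, 3)
  tab[2:3, 2:3] <- f_hi
  penetrance_model("custom_table", table = array(tab, dim = c(3, 3)),
                   mafs = c(maf, maf))
}
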