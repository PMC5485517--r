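#' Chi-squared test of association on a k-locus contingency table
#'
#' Statistic of independence between genotype combination and disease status,
#' summed over rows with a positive margin; the degrees of freedom stay at
#' `3^k - 1` regardless of empty rows, so critical values remain comparable
#' across combinations of the same order (df = 8 for pairs, 26 for triples,
#' 80 for quadruples).
#'
#' @param table a [contingency_table()] or a plain `3^k x 2` count matrix
#'   (columns case, control).
#' @return A list of class `epi_test` with `statistic`, `df` and `p_value`.
#' @export
chi_squared_test <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts
            else as.matrix(table)
  if (ncol(counts) != 2L) stop("table must have two columns (case, control)")
  cm <- colSums(counts)
  if (any(cm <= 0))
    stop("degenerate design: a case/control margin is zero")
  N <- sum(cm)
  rm <- rowSums(counts)
  keep <- rm > 0
  e <- outer(rm[keep], cm) / N
  stat <- sum((counts[keep, , drop = FALSE] - e)^2 / e)
  df <- nrow(counts) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df = df, lower.tail = FALSE)),
            class = "epi_test")
}

#' @export
print.epi_test <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Bonferroni-corrected significance level for an order-k scan
#'
#' `alpha0 / choose(M, k)`: the preset level divided by the number of
#' order-k combinations among M SNPs.
#'
#' @param alpha0 preset significance level.
#' @param M number of SNPs.
#' @param k interaction order (>= 1).
#' @return The corrected level.
#' @export
bonferroni_level <- function(alpha0, M, k = 2L) {
  stopifnot(alpha0 > 0, alpha0 < 1)
  if (M < k) stop("M must be >= k")
  alpha0 / choose(M, k)
}

#' Critical chi-squared statistic at a significance level
#'
#' Inverse upper-tail chi-squared quantile: the statistic whose upper-tail
#' probability equals `level`.
#'
#' @param level significance level in (0, 1).
#' @param df degrees of freedom.
#' @return The critical statistic.
#' @export
critical_statistic <- function(level, df) {
  if (any(level <= 0) || any(level >= 1))
    stop("level must lie strictly in (0, 1)")
  qchisq(level, df = df, lower.tail = FALSE)
}

#' Two-threshold significance scheme for the pairwise scan
#'
#' Bonferroni level `alpha = alpha0 / choose(M, 2)` defines "significant"
#' pairs; the relaxed intermediate level `alpha' = omega * alpha` (capped at
#' 1) defines the retention band. Critical statistics are at df = 8.
#'
#' @param M number of SNPs.
#' @param alpha0 preset significance level (default 0.05).
#' @param omega scale factor >= 1 widening the intermediate band
#'   (default `1e4`). Larger `omega` retains more pairs at higher runtime.
#' @return A list of class `significance_scheme` with `alpha0`, `M`, `omega`,
#'   `alpha`, `alpha_prime`, `chi2_alpha`, `chi2_alpha_prime`.
#' @export
significance_scheme <- function(M, alpha0 = 0.05, omega = 1e4) {
  stopifnot(M >= 2, omega >= 1)
  alpha <- bonferroni_level(alpha0, M, 2L)
  alpha_prime <- min(omega * alpha, 1)
  structure(list(alpha0 = alpha0, M = as.integer(M), omega = omega,
                 alpha = alpha, alpha_prime = alpha_prime,
                 chi2_alpha = critical_statistic(alpha, 8L),
                 chi2_alpha_prime =
                   if (alpha_prime >= 1) 0 else
                     critical_statistic(alpha_prime, 8L)),
            class = "significance_scheme")
}

#' @export
print.significance_scheme <- function(x, ...) {
  cat(sprintf(paste0("Significance scheme: alpha0 = %g, M = %d, omega = %g\n",
                     "  alpha = %.4g (chi2 > %.3f), alpha' = %.4g (chi2 > %.3f)\n"),
              x$alpha0, x$M, x$omega, x$alpha, x$chi2_alpha,
              x$alpha_prime, x$chi2_alpha_prime))
  invisible(x)
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

#' Fit a logistic regression by Newton-Raphson
#'
#' Maximizes the binomial log-likelihood of `y` on a design matrix (which
#' must already contain an intercept column if one is wanted). Degenerate
#' columns (all-zero or linearly dependent) are pruned before fitting.
#' Convergence is declared when the log-likelihood changes by less than
#' `tol`, up to `max_iter` iterations. Complete separation (diverging
#' coefficients) is resolved by adding a ridge of `1e-6` to the Hessian and
#' flagged in the result.
#'
#' @param X numeric design matrix (rows = samples).
#' @param y binary response vector.
#' @param tol convergence tolerance on the log-likelihood (default `1e-8`).
#' @param max_iter maximum Newton iterations (default 50).
#' @return A list with `coefficients` (NA for pruned columns), `logLik`,
#'   `iterations`, `converged`, `separation`, `kept` (indices of retained
#'   columns).
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  p_all <- ncol(X)
  # prune all-zero / linearly dependent columns
  qrX <- qr(X)
  kept <- sort(qrX$pivot[seq_len(qrX$rank)])
  Xk <- X[, kept, drop = FALSE]
  p <- ncol(Xk)
  beta <- numeric(p)
  ll_old <- -Inf
  separation <- FALSE
  ridge <- 0
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    eta <- drop(Xk %*% beta)
    mu <- plogis(eta)
    ll <- sum(y * eta - log1pexp(eta))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    ll_old <- ll
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Xk, Xk * w)
    if (ridge > 0) H <- H + diag(ridge, p)
    g <- crossprod(Xk, y - mu)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      separation <- TRUE
      ridge <- 1e-6
      H <- H + diag(ridge, p)
      step <- solve(H, g)
    }
    beta <- beta + drop(step)
    if (max(abs(beta)) > 15 || !all(is.finite(beta))) {
      # diverging norm: complete or quasi-complete separation
      separation <- TRUE
      ridge <- 1e-6
      beta[!is.finite(beta)] <- 0
      beta <- pmin(pmax(beta, -1e3), 1e3)
    }
  }
  coef_all <- rep(NA_real_, p_all)
  coef_all[kept] <- beta
  names(coef_all) <- colnames(X)
  list(coefficients = coef_all, logLik = ll, iterations = iter,
       converged = converged, separation = separation, kept = kept)
}

# two indicator columns (g == 1, g == 2) for one SNP's genotype vector
indicator_pair <- function(g, tag) {
  m <- cbind(as.numeric(g == 1L), as.numeric(g == 2L))
  colnames(m) <- paste0(tag, c("_1", "_2"))
  m
}

#' Likelihood-ratio deviance of a SNP pair against its main effects
#'
#' Fits a full logistic model (intercept, two genotype indicators per SNP and
#' their four pairwise products; genotypes treated as categorical with
#' baseline 0) and a reduced model holding only the indicators of the SNPs
#' flagged as having a strong main effect. The deviance
#' `D = 2 (logL_full - logL_reduced)` is referred to a chi-squared
#' distribution with df = 4 when both SNPs are flagged and df = 6 when only
#' one is. Genotype levels absent from the analyzed samples have their
#' indicators pruned from both models and the df reduced accordingly
#' (recorded in `pruned`). Samples missing at either SNP are excluded.
#'
#' @param ds a [genotype_dataset()].
#' @param pair integer vector of two SNP indices.
#' @param flags logical vector of length 2: which SNPs of the pair carry a
#'   strong main effect (at least one must be `TRUE`).
#' @return A list of class `lrt_result` with `deviance`, `df`, `p_value`,
#'   `logL_full`, `logL_reduced`, `flags`, `pruned` (number of design columns
#'   pruned from the full model) and `separation`.
#' @export
lrt_deviance <- function(ds, pair, flags) {
  stopifnot(inherits(ds, "genotype_dataset"), length(pair) == 2L,
            length(flags) == 2L)
  flags <- as.logical(flags)
  if (!any(flags)) stop("at least one SNP of the pair must be flagged")
  g1 <- ds$genotypes[, pair[1L]]
  g2 <- ds$genotypes[, pair[2L]]
  cc <- !is.na(g1) & !is.na(g2)
  g1 <- g1[cc]; g2 <- g2[cc]
  y <- ds$phenotype[cc]
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L)
    stop("both SNPs must be polymorphic in the analyzed samples")
  i1 <- indicator_pair(g1, "x1")
  i2 <- indicator_pair(g2, "x2")
  inter <- cbind(i1[, 1L] * i2[, 1L], i1[, 1L] * i2[, 2L],
                 i1[, 2L] * i2[, 1L], i1[, 2L] * i2[, 2L])
  colnames(inter) <- c("x1_1:x2_1", "x1_1:x2_2", "x1_2:x2_1", "x1_2:x2_2")
  # drop indicators for absent genotype levels from both models
  keep1 <- colSums(i1) > 0
  keep2 <- colSums(i2) > 0
  i1 <- i1[, keep1, drop = FALSE]
  i2 <- i2[, keep2, drop = FALSE]
  inter <- inter[, colSums(inter) > 0, drop = FALSE]
  X_full <- cbind(`(Intercept)` = 1, i1, i2, inter)
  red_cols <- list()
  if (flags[1L]) red_cols <- c(red_cols, list(i1))
  if (flags[2L]) red_cols <- c(red_cols, list(i2))
  X_red <- do.call(cbind, c(list(`(Intercept)` = 1), red_cols))
  fit_f <- fit_logistic(X_full, y)
  fit_r <- fit_logistic(X_red, y)
  df <- length(fit_f$kept) - length(fit_r$kept)
  if (df < 1L) df <- 1L
  D <- 2 * (fit_f$logLik - fit_r$logLik)
  if (D < 0 && D > -1e-6) D <- 0
  structure(list(deviance = D, df = df,
                 p_value = pchisq(D, df = df, lower.tail = FALSE),
                 logL_full = fit_f$logLik, logL_reduced = fit_r$logLik,
                 flags = flags,
                 pruned = (9L - ncol(X_full)) ,
                 separation = fit_f$separation || fit_r$separation),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT deviance = %.4g, df = %d, p = %.4g (flags: %s)\n",
              x$deviance, x$df, x$p_value,
              paste(ifelse(x$flags, "strong", "-"), collapse = ", ")))
  invisible(x)
}
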