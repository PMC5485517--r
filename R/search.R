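#' Ant colony optimization configuration
#'
#' Defaults follow the recommended settings for candidate sets of size `W`:
#' `n_ants` and `max_iter` both scale as `0.1 W` (`n_ants` clamped to
#' `[500, 5000]`), initial pheromone `tau0 = 100`, evaporation `rho = 0.05`,
#' `d = 2` pairs per ant for three-locus detection, selection weights
#' `delta = beta = eta = 1`, three-SNP fitness scale `fs = 2` (a merged
#' three-SNP statistic is roughly half the critical value of a four-SNP one,
#' so it is scaled to avoid losing significant triples), and a global list of
#' the `top_t = 100` best merged combinations.
#'
#' @param W number of candidate pairs.
#' @param tau0 initial pheromone value.
#' @param n_ants number of ants per iteration.
#' @param rho evaporation coefficient in (0, 1).
#' @param d pairs selected per ant (>= 2).
#' @param max_iter number of iterations.
#' @param delta,beta pheromone/prior weights in the selection rule.
#' @param eta prior information per candidate (scalar or length-W vector).
#' @param fs fitness scale factor applied to merged three-SNP combinations.
#' @param top_t size of the stored best-combination list.
#' @param seed optional RNG seed for reproducible searches.
#' @return A list of class `aco_config`.
#' @export
aco_config <- function(W, tau0 = 100, n_ants = NULL, rho = 0.05, d = 2L,
                       max_iter = NULL, delta = 1, beta = 1, eta = 1,
                       fs = 2, top_t = 100L, seed = NULL) {
  stopifnot(W >= 1)
  if (is.null(n_ants)) n_ants <- as.integer(min(5000, max(500, round(0.1 * W))))
  if (is.null(max_iter)) max_iter <- as.integer(max(1, round(0.1 * W)))
  if (d < 2L || d > W) stop("d must lie in [2, W]")
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (fs < 1) stop("fs must be >= 1")
  structure(list(W = as.integer(W), tau0 = tau0, n_ants = as.integer(n_ants),
                 rho = rho, d = as.integer(d),
                 max_iter = as.integer(max_iter), delta = delta, beta = beta,
                 eta = eta, fs = fs, top_t = as.integer(top_t), seed = seed),
            class = "aco_config")
}

# selection probabilities of Eq. tau^delta * eta^beta / sum
selection_probs <- function(tau, config) {
  w <- tau^config$delta * config$eta^config$beta
  w / sum(w)
}

#' Roulette-wheel selection of a candidate pair
#'
#' Returns index `i` with probability
#' `tau_i^delta eta_i^beta / sum_j tau_j^delta eta_j^beta`.
#'
#' @param tau positive pheromone vector (one entry per candidate pair).
#' @param config an [aco_config()].
#' @return A single 1-based candidate index.
#' @export
select_pair <- function(tau, config) {
  stopifnot(length(tau) >= 1, all(tau > 0))
  sample.int(length(tau), 1L, prob = selection_probs(tau, config))
}

#' Merge selected candidate pairs and score the union
#'
#' The SNPs of the selected pairs are merged into a set `S`; the chi-squared
#' statistic of its `3^|S| x 2` contingency table is the fitness, multiplied
#' by `fs` when `|S| = 3` (to keep three-SNP merges competitive with
#' four-SNP ones, whose critical value is about twice as large).
#'
#' @param picked matrix with one row per selected pair and two columns of SNP
#'   indices (or a list of length-2 vectors).
#' @param bits a [bit_encode()]d dataset.
#' @param config an [aco_config()] (only `fs` is used).
#' @return A list of class `merged_combination` with `snps` (sorted union),
#'   `chi2`, `df`, `fitness`.
#' @export
merge_and_score <- function(picked, bits, config) {
  if (is.list(picked)) picked <- do.call(rbind, picked)
  snps <- sort(unique(as.integer(picked)))
  chi2 <- cpp_chi2_subsets(bits$case, bits$control,
                           matrix(snps, ncol = 1L))
  df <- 3L^length(snps) - 1L
  fitness <- if (length(snps) == 3L) config$fs * chi2 else chi2
  structure(list(snps = snps, chi2 = as.numeric(chi2), df = df,
                 fitness = as.numeric(fitness)),
            class = "merged_combination")
}

#' Pheromone update with evaporation and fitness deposits
#'
#' Every candidate evaporates once per iteration, `tau_i <- (1 - rho) tau_i`;
#' each candidate selected by an ant additionally receives a deposit of
#' `0.01 x` that ant's fitness. Deposits from multiple ants accumulate.
#'
#' @param tau pheromone vector.
#' @param ant_results list of ants, each a list with `picked` (candidate
#'   indices) and `fitness`.
#' @param config an [aco_config()] (only `rho` is used).
#' @return The updated pheromone vector.
#' @export
update_pheromones <- function(tau, ant_results, config) {
  tau <- (1 - config$rho) * tau
  for (ant in ant_results)
    tau[ant$picked] <- tau[ant$picked] + 0.01 * ant$fitness
  tau
}

# shared final step: evaluate K-subsets of stored SNP sets, Bonferroni filter
report_k_subsets <- function(snp_sets, bits, K, alpha0, M) {
  sets <- Filter(function(s) length(s) >= K, snp_sets)
  if (!length(sets))
    return(empty_interactions(K))
  subs <- unique(do.call(cbind, lapply(sets, function(s)
    combn(sort(s), K))), MARGIN = 2L)
  chi2 <- cpp_chi2_subsets(bits$case, bits$control, subs)
  df <- 3L^K - 1L
  p <- pchisq(chi2, df = df, lower.tail = FALSE)
  level <- bonferroni_level(alpha0, M, K)
  keep <- which(!is.na(p) & p < level)
  if (!length(keep)) {
    out <- empty_interactions(K)
    out$bonferroni_level <- numeric(0)
    return(out)
  }
  out <- as.data.frame(t(subs[, keep, drop = FALSE]))
  names(out) <- paste0("snp", seq_len(K))
  out$chi2 <- chi2[keep]
  out$df <- df
  out$p <- p[keep]
  out$bonferroni_level <- level
  out <- out[order(out$p, out[[1L]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_interactions <- function(K) {
  out <- as.data.frame(setNames(rep(list(integer(0)), K),
                                paste0("snp", seq_len(K))))
  out$chi2 <- numeric(0); out$df <- integer(0); out$p <- numeric(0)
  out$bonferroni_level <- numeric(0)
  out
}

candidate_pair_matrix <- function(candidates) {
  if (inherits(candidates, "screen_result"))
    candidates <- candidates$candidates
  if (is.data.frame(candidates))
    candidates <- cbind(candidates$snp_a, candidates$snp_b)
  m <- as.matrix(candidates)
  storage.mode(m) <- "integer"
  if (ncol(m) != 2L) stop("candidates must be pairs (two columns)")
  m
}

#' Exhaustive K-locus search over the merged candidate SNP set
#'
#' Merges all SNPs appearing in the candidate pairs into a set `S` and
#' evaluates every K-subset of `S` by [chi_squared_test()] (df = `3^K - 1`),
#' reporting subsets with p-value below the Bonferroni level
#' `alpha0 / choose(M, K)`, sorted by ascending p-value.
#'
#' @param candidates a [screen()] result, its `candidates` data frame, or a
#'   two-column matrix of SNP index pairs.
#' @param bits a [bit_encode()]d dataset.
#' @param K interaction order (>= 3).
#' @param alpha0 preset significance level.
#' @param M total number of SNPs (for the Bonferroni level); defaults to
#'   `bits$M`.
#' @return Data frame with columns `snp1..snpK`, `chi2`, `df`, `p`,
#'   `bonferroni_level`; empty (zero rows) when `|S| < K`.
#' @export
exhaustive_search <- function(candidates, bits, K = 3L, alpha0 = 0.05,
                              M = bits$M) {
  stopifnot(inherits(bits, "bit_dataset"), K >= 3L)
  pm <- candidate_pair_matrix(candidates)
  S <- sort(unique(as.integer(pm)))
  if (length(S) < K) return(empty_interactions(K))
  report_k_subsets(list(S), bits, K, alpha0, M)
}

#' Ant-colony-optimization K-locus search
#'
#' Pheromones start at `tau0` for each candidate pair. In every iteration
#' each of `n_ants` ants selects `d` distinct pairs by roulette-wheel
#' selection (probability proportional to `tau^delta eta^beta`), merges them
#' and scores the union with the chi-squared statistic of its contingency
#' table (scaled by `fs` for three-SNP unions); the best `top_t` merged
#' combinations by fitness are kept in a global list. After all ants of an
#' iteration are evaluated, pheromones evaporate by `rho` and selected pairs
#' receive deposits of `0.01 x` fitness. Finally every K-subset of each
#' stored combination is tested and those with p-value below
#' `alpha0 / choose(M, K)` are reported (deduplicated, ascending p).
#' Fully reproducible given `config$seed`.
#'
#' @inheritParams exhaustive_search
#' @param config an [aco_config()]; its `W` must match the candidate count.
#' @return Data frame as in [exhaustive_search()].
#' @export
aco_search <- function(candidates, bits, K = 3L, config = NULL,
                       alpha0 = 0.05, M = bits$M) {
  stopifnot(inherits(bits, "bit_dataset"), K >= 3L)
  pm <- candidate_pair_matrix(candidates)
  W <- nrow(pm)
  if (is.null(config)) config <- aco_config(W)
  if (config$d > W) stop("d exceeds the number of candidates W")
  if (!is.null(config$seed)) set.seed(config$seed)
  tau <- rep(config$tau0, W)
  # global best list: named fitness vector, names = canonical SNP-set keys
  best_fit <- numeric(0)
  best_sets <- list()
  eta_v <- rep(config$eta, length.out = W)
  for (it in seq_len(config$max_iter)) {
    pr <- tau^config$delta * eta_v^config$beta
    pr <- pr / sum(pr)
    picks <- matrix(0L, config$n_ants, config$d)
    picks[, 1L] <- sample.int(W, config$n_ants, replace = TRUE, prob = pr)
    for (dd in 2L:config$d) {
      cand <- sample.int(W, config$n_ants, replace = TRUE, prob = pr)
      # per-ant selection is without replacement: redraw collisions
      repeat {
        clash <- rowSums(picks[, seq_len(dd - 1L), drop = FALSE] == cand) > 0
        if (!any(clash)) break
        cand[clash] <- sample.int(W, sum(clash), replace = TRUE, prob = pr)
      }
      picks[, dd] <- cand
    }
    # merged SNP unions per ant
    unions <- lapply(seq_len(config$n_ants), function(a)
      sort(unique(as.integer(pm[picks[a, ], ]))))
    sizes <- lengths(unions)
    fitness <- numeric(config$n_ants)
    for (sz in unique(sizes)) {
      idx <- which(sizes == sz)
      subs <- vapply(unions[idx], identity, integer(sz))
      chi2 <- cpp_chi2_subsets(bits$case, bits$control,
                               matrix(subs, nrow = sz))
      chi2[is.na(chi2)] <- 0
      fitness[idx] <- if (sz == 3L) config$fs * chi2 else chi2
    }
    # update global top list
    keys <- vapply(unions, paste, character(1), collapse = "-")
    newk <- !duplicated(keys) & !(keys %in% names(best_fit))
    if (any(newk)) {
      add <- setNames(fitness[newk], keys[newk])
      best_sets[keys[newk]] <- unions[newk]
      best_fit <- c(best_fit, add)
      # fitness of an already-stored set is deterministic, no need to update
      if (length(best_fit) > config$top_t) {
        ord <- order(-best_fit)[seq_len(config$top_t)]
        best_fit <- best_fit[ord]
        best_sets <- best_sets[names(best_fit)]
      }
    }
    # pheromone update: evaporate all, deposit on selected
    tau <- (1 - config$rho) * tau
    dep <- rep(fitness, config$d)
    upd <- tapply(0.01 * dep, as.integer(picks), sum)
    tau[as.integer(names(upd))] <- tau[as.integer(names(upd))] + upd
  }
  out <- report_k_subsets(best_sets, bits, K, alpha0, M)
  attr(out, "pheromones") <- tau
  out
}

#' Stage 2: dispatch the K-locus interaction search
#'
#' Exhaustive search is used when the number of candidate pairs `W` is small
#' (`W < 2000`); otherwise ant colony optimization. The user can force
#' either branch with `strategy`.
#'
#' @inheritParams aco_search
#' @param strategy `"auto"`, `"exhaustive"` or `"aco"`.
#' @param w_exhaustive threshold on W below which the auto strategy picks
#'   exhaustive search (default 2000).
#' @return Data frame as in [exhaustive_search()], with the chosen strategy
#'   in attribute `strategy`.
#' @export
run_stage2 <- function(candidates, bits, K = 3L,
                       strategy = c("auto", "exhaustive", "aco"),
                       config = NULL, alpha0 = 0.05, M = bits$M,
                       w_exhaustive = 2000L) {
  strategy <- match.arg(strategy)
  pm <- candidate_pair_matrix(candidates)
  W <- nrow(pm)
  if (W < 1L) stop("candidate set is empty")
  if (strategy == "auto")
    strategy <- if (W < w_exhaustive) "exhaustive" else "aco"
  out <- if (strategy == "exhaustive") {
    exhaustive_search(pm, bits, K = K, alpha0 = alpha0, M = M)
  } else {
    if (is.null(config)) config <- aco_config(W)
    aco_search(pm, bits, K = K, config = config, alpha0 = alpha0, M = M)
  }
  attr(out, "strategy") <- strategy
  out
}
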