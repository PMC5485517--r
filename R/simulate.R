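#' Hardy-Weinberg genotype sampling
#'
#' Draws i.i.d. genotypes with probabilities
#' `((1-p)^2, 2p(1-p), p^2)` for codes 0/1/2, i.e. `Binomial(2, maf)`.
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @param n number of genotypes to draw.
#' @return Integer vector of genotype codes.
#' @export
genotypes_hwe <- function(maf, n) {
  stopifnot(maf >= 0, maf <= 0.5, n >= 0)
  rbinom(n, 2L, maf)
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# annotate a penetrance table (array dim rep(3, k)) with derived quantities
annotate_model <- function(table, mafs, family, params = list()) {
  k <- length(mafs)
  table <- array(as.numeric(table), dim = rep(3L, k))
  if (any(table < 0 | table > 1))
    stop("penetrance values must lie in [0, 1]")
  probs_per_locus <- lapply(mafs, hwe_probs)
  joint <- Reduce(function(a, b) outer(a, b), probs_per_locus)
  joint <- array(joint, dim = rep(3L, k))
  prevalence <- sum(joint * table)
  if (prevalence <= 0 || prevalence >= 1)
    stop("model prevalence must lie in (0, 1)")
  marg <- matrix(NA_real_, k, 3L,
                 dimnames = list(NULL, c("P_AA", "P_Aa", "P_aa")))
  for (i in seq_len(k)) {
    for (g in 0:2) {
      sel <- slice.index(table, i) == g + 1L
      w <- joint
      # condition on locus i = g: renormalize the other loci's HWE weights
      pi_g <- probs_per_locus[[i]][g + 1L]
      marg[i, g + 1L] <- sum(table[sel] * joint[sel]) / pi_g
    }
  }
  odds <- function(p) p / (1 - p)
  lambdas <- vapply(seq_len(k), function(i) {
    paa <- marg[i, 1L]; pab <- marg[i, 2L]
    if (paa <= 0 || paa >= 1) return(NA_real_)
    odds(pab) / odds(paa) - 1
  }, numeric(1))
  h2 <- sum(joint * (table - prevalence)^2) /
    (prevalence * (1 - prevalence))
  structure(list(k = k, mafs = mafs, table = table, prevalence = prevalence,
                 marginal_penetrances = marg, lambdas = lambdas, h2 = h2,
                 family = family, params = params),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("Penetrance model '%s': %d loci, MAF %s\n", x$family, x$k,
              paste(signif(x$mafs, 3), collapse = "/")))
  cat(sprintf("  prevalence = %.4g, h2 = %.4g\n", x$prevalence, x$h2))
  cat(sprintf("  marginal effect sizes lambda: %s\n",
              paste(signif(x$lambdas, 4), collapse = ", ")))
  invisible(x)
}

#' Marginal effect size of a disease locus
#'
#' `lambda = odds(P_Aa) / odds(P_AA) - 1`, where `P_AA` and `P_Aa` are the
#' marginal penetrances of the common homozygote and the heterozygote at the
#' locus (the penetrance table summed over the other loci with their
#' Hardy-Weinberg genotype weights).
#'
#' @param model a [penetrance_model()].
#' @param locus 1-based locus index.
#' @return The effect size `lambda`.
#' @export
marginal_effect_size <- function(model, locus) {
  stopifnot(inherits(model, "penetrance_model"),
            locus >= 1, locus <= model$k)
  paa <- model$marginal_penetrances[locus, 1L]
  pab <- model$marginal_penetrances[locus, 2L]
  if (paa <= 0 || paa >= 1)
    stop("marginal penetrance P_AA in {0, 1}: odds undefined")
  unname((pab / (1 - pab)) / (paa / (1 - paa)) - 1)
}

#' Build a parameterized penetrance model
#'
#' Families:
#' \describe{
#'   \item{`multiplicative3`}{Three-locus multiplicative interaction on the
#'     odds scale, `f(g) / (1 - f(g)) = a (1 + theta)^(g1 g2 g3)`; `theta`
#'     is calibrated by root-finding so that the per-locus marginal effect
#'     size equals `lambda` at the given `maf`, with the baseline `a` solved
#'     at each `theta` so the prevalence matches its target.}
#'   \item{`threshold3`}{Three-locus threshold interaction,
#'     `f(g) / (1 - f(g)) = a (1 + theta)` iff `min(g1, g2, g3) >= 1`, else
#'     `a`; calibrated like `multiplicative3`.}
#'   \item{`pure3`}{Pure three-locus epistasis at MAF fixed to 0.5:
#'     `f(g) = p_hi` iff `g1 + g2 + g3` is odd, else `p_lo`. The parity
#'     construction makes all marginal penetrances equal (all `lambda = 0`)
#'     for any `(p_hi, p_lo)`; the two values are solved so the heritability
#'     equals `h2`. With `prevalence = NULL` (default) the low class is set
#'     to `p_lo = 0`, giving `P(D) = h2 / (1 + h2)`; a user-supplied
#'     prevalence is honored when feasible (`h2 <= P / (1 - P)`).}
#'   \item{`custom_table`}{User-supplied penetrance table over `3^k`
#'     genotype combinations (array of dim `rep(3, k)`, first locus = first
#'     dimension), validated and annotated.}
#' }
#'
#' @param family model family (see Details).
#' @param maf minor allele frequency of the disease loci (scalar; `pure3`
#'   requires 0.5).
#' @param lambda target marginal effect size (`multiplicative3`,
#'   `threshold3`).
#' @param h2 target heritability (`pure3`).
#' @param prevalence target disease prevalence (baseline for the calibrated
#'   families, default 0.01; optional for `pure3`).
#' @param table penetrance array for `custom_table`.
#' @param mafs per-locus MAF vector for `custom_table`.
#' @return A `penetrance_model` object with the table and derived
#'   annotations (prevalence, marginal penetrances, `lambdas`, `h2`).
#' @export
penetrance_model <- function(family = c("multiplicative3", "threshold3",
                                        "pure3", "custom_table"),
                             maf = NULL, lambda = NULL, h2 = NULL,
                             prevalence = NULL, table = NULL, mafs = NULL) {
  family <- match.arg(family)
  if (family == "custom_table") {
    if (is.null(table) || is.null(mafs))
      stop("custom_table requires `table` and `mafs`")
    return(annotate_model(table, mafs, family))
  }
  if (family == "pure3") {
    if (is.null(h2)) stop("pure3 requires a target h2")
    if (is.null(maf)) maf <- 0.5
    if (abs(maf - 0.5) > 1e-12)
      stop("pure3 is defined at MAF = 0.5")
    if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
    if (is.null(prevalence)) {
      P <- h2 / (1 + h2)
      p_lo <- 0
      p_hi <- 2 * P
    } else {
      P <- prevalence
      if (h2 > P / (1 - P) + 1e-12)
        stop(sprintf(paste0("h2 = %g unattainable at prevalence %g with the",
                            " parity construction; need h2 <= %g"),
                     h2, P, P / (1 - P)))
      delta <- 2 * sqrt(h2 * P * (1 - P))
      p_hi <- P + delta / 2
      p_lo <- P - delta / 2
    }
    if (p_hi > 1) stop("infeasible pure3 target (p_hi > 1)")
    g <- expand.grid(0:2, 0:2, 0:2)
    odd <- (g[[1L]] + g[[2L]] + g[[3L]]) %% 2L == 1L
    tab <- array(ifelse(odd, p_hi, p_lo), dim = c(3, 3, 3))
    return(annotate_model(tab, rep(0.5, 3), family,
                          params = list(h2_target = h2, p_hi = p_hi,
                                        p_lo = p_lo)))
  }
  # calibrated marginal-effect families
  if (is.null(maf)) stop(family, " requires `maf`")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  if (is.null(lambda))
    lambda <- if (family == "multiplicative3") 0.2 else 0.3
  if (is.null(prevalence)) prevalence <- 0.01
  g <- expand.grid(0:2, 0:2, 0:2)
  shape <- if (family == "multiplicative3") {
    function(theta) (1 + theta)^(g[[1L]] * g[[2L]] * g[[3L]])
  } else {
    function(theta) ifelse(pmin(g[[1L]], g[[2L]], g[[3L]]) >= 1L,
                           1 + theta, 1)
  }
  probs <- hwe_probs(maf)
  joint <- probs[g[[1L]] + 1L] * probs[g[[2L]] + 1L] * probs[g[[3L]] + 1L]
  model_at <- function(theta) {
    s <- shape(theta)  # odds multiplier per genotype combination
    # solve baseline a (log scale) so the prevalence hits its target
    pfun <- function(loga) {
      ao <- exp(loga) * s
      sum(joint * ao / (1 + ao)) - prevalence
    }
    a <- exp(uniroot(pfun, c(-35, 15), tol = 1e-14)$root)
    odds_tab <- a * s
    tab <- array(odds_tab / (1 + odds_tab), dim = c(3, 3, 3))
    annotate_model(tab, rep(maf, 3), family,
                   params = list(theta = theta, a = a,
                                 lambda_target = lambda))
  }
  obj <- function(theta) {
    m <- tryCatch(model_at(theta), error = function(e) NULL)
    if (is.null(m)) return(NA_real_)
    m$lambdas[1L] - lambda
  }
  upper <- 1
  while (is.finite(obj(upper)) && obj(upper) < 0 && upper < 1e6)
    upper <- upper * 4
  if (!is.finite(obj(upper)) || obj(upper) < 0)
    stop(sprintf(paste0("calibration failure: lambda = %g unattainable at ",
                        "maf = %g, prevalence = %g (max feasible lambda ",
                        "~ %.4g)"),
                 lambda, maf, prevalence,
                 max(vapply(seq(0.1, upper, length.out = 50), function(t) {
                   v <- obj(t); if (is.na(v)) -Inf else v + lambda
                 }, numeric(1)))))
  theta <- uniroot(obj, c(0, upper), tol = 1e-12)$root
  model_at(theta)
}

#' Simulation configuration
#'
#' @param M total number of SNPs.
#' @param n_case,n_control case and control sample counts.
#' @param background_maf_range MAF interval for background (non-disease)
#'   SNPs, drawn uniformly per SNP.
#' @param r2 linkage disequilibrium between each disease locus and its
#'   genotyped marker, in (0, 1]; `r2 = 1` genotypes the disease loci
#'   directly.
#' @param seed RNG seed.
#' @param n_datasets number of replicates for power estimation.
#' @param max_draws budget on total individuals drawn while filling the
#'   case/control quota.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(M = 1000L, n_case = 1000L, n_control = 1000L,
                       background_maf_range = c(0.05, 0.5), r2 = 1,
                       seed = NULL, n_datasets = 100L, max_draws = 2e6) {
  stopifnot(M >= 3, n_case >= 1, n_control >= 1, r2 > 0, r2 <= 1,
            length(background_maf_range) == 2L,
            background_maf_range[1L] <= background_maf_range[2L])
  structure(list(M = as.integer(M), n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 background_maf_range = background_maf_range, r2 = r2,
                 seed = seed, n_datasets = as.integer(n_datasets),
                 max_draws = max_draws),
            class = "sim_config")
}

#' Marker genotypes in linkage disequilibrium with a disease locus
#'
#' Equal-frequency haplotype coupling: per haplotype the marker allele copies
#' the disease allele with probability `1 - eps` and is an independent
#' frequency-matched draw with probability `eps`, where
#' `eps = 1 - sqrt(r2)`; the haplotype correlation is then `sqrt(r2)` and
#' the locus-marker LD equals `r2`. With `r2 = 1` the marker equals the
#' disease locus.
#'
#' @param h1,h2 binary disease-locus haplotype allele vectors (one pair per
#'   individual).
#' @param maf allele frequency of the disease (and marker) locus.
#' @param r2 target LD in (0, 1].
#' @return List with `genotype` (marker genotype vector `m1 + m2`) and the
#'   marker haplotypes `m1`, `m2`.
#' @export
ld_marker <- function(h1, h2, maf, r2) {
  stopifnot(r2 > 0, r2 <= 1, length(h1) == length(h2))
  eps <- 1 - sqrt(r2)
  couple <- function(h) {
    n <- length(h)
    redraw <- runif(n) < eps
    m <- h
    m[redraw] <- rbinom(sum(redraw), 1L, maf)
    m
  }
  m1 <- couple(h1)
  m2 <- couple(h2)
  list(genotype = as.integer(m1 + m2), m1 = m1, m2 = m2)
}

#' Sample a case-control dataset under a penetrance model
#'
#' Individuals are drawn with disease-locus genotypes at the model MAFs and
#' background-SNP genotypes at MAFs uniform in `background_maf_range` (all
#' Hardy-Weinberg), and assigned case status with probability equal to the
#' penetrance of their disease-locus genotype combination; drawing continues
#' until exactly `n_case` cases and `n_control` controls are accumulated.
#' With `r2 < 1` the disease loci themselves are not genotyped; markers in
#' LD `r2` with them ([ld_marker()]) are placed in the dataset instead, and
#' the truth record points at the marker columns.
#'
#' @param model a [penetrance_model()].
#' @param cfg a [sim_config()].
#' @return List with `dataset` (a [genotype_dataset()], cases first) and
#'   `truth` (list with `disease_cols`, the genotyped disease/marker column
#'   indices, and the model).
#' @export
sample_case_control <- function(model, cfg) {
  stopifnot(inherits(model, "penetrance_model"), inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- model$k
  if (cfg$M < k) stop("M must be at least the number of disease loci")
  P <- model$prevalence
  need_case <- cfg$n_case
  need_ctrl <- cfg$n_control
  acc_g <- vector("list", 0L)  # accepted genotyped disease/marker rows
  acc_y <- integer(0)
  drawn <- 0L
  while (need_case > 0L || need_ctrl > 0L) {
    batch <- as.integer(min(
      max(200, 1.4 * (need_case / max(P, 1e-6) +
                        need_ctrl / max(1 - P, 1e-6))),
      cfg$max_draws - drawn))
    if (batch <= 0L)
      stop(sprintf(paste0("draw budget exhausted (%g individuals): model ",
                          "prevalence %.4g too extreme for the requested ",
                          "quota"), cfg$max_draws, P))
    drawn <- drawn + batch
    # disease-locus haplotypes -> genotypes
    H1 <- matrix(rbinom(batch * k, 1L, rep(model$mafs, each = batch)),
                 batch, k)
    H2 <- matrix(rbinom(batch * k, 1L, rep(model$mafs, each = batch)),
                 batch, k)
    G <- H1 + H2
    # flattened penetrance-table index (first locus = first array dimension)
    idx <- as.integer(G %*% (3L^(seq_len(k) - 1L))) + 1L
    f <- as.vector(model$table)[idx]
    y <- as.integer(runif(batch) < f)
    # genotyped columns: the loci themselves (r2 = 1) or LD markers
    if (cfg$r2 < 1) {
      Gm <- matrix(0L, batch, k)
      for (j in seq_len(k))
        Gm[, j] <- ld_marker(H1[, j], H2[, j], model$mafs[j], cfg$r2)$genotype
    } else {
      Gm <- G
    }
    take_case <- which(y == 1L)[seq_len(min(need_case, sum(y == 1L)))]
    take_ctrl <- which(y == 0L)[seq_len(min(need_ctrl, sum(y == 0L)))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      acc_g <- c(acc_g, list(Gm[take, , drop = FALSE]))
      acc_y <- c(acc_y, y[take])
    }
    need_case <- need_case - length(take_case)
    need_ctrl <- need_ctrl - length(take_ctrl)
  }
  Gd <- do.call(rbind, acc_g)
  ord <- order(-acc_y)  # cases first
  Gd <- Gd[ord, , drop = FALSE]
  y <- acc_y[ord]
  n <- length(y)
  # place disease/marker columns at random positions among M SNPs
  disease_cols <- sort(sample.int(cfg$M, k))
  geno <- matrix(0L, n, cfg$M)
  bg_cols <- setdiff(seq_len(cfg$M), disease_cols)
  bg_maf <- runif(length(bg_cols), cfg$background_maf_range[1L],
                  cfg$background_maf_range[2L])
  for (jj in seq_along(bg_cols))
    geno[, bg_cols[jj]] <- rbinom(n, 2L, bg_maf[jj])
  geno[, disease_cols] <- Gd
  ds <- genotype_dataset(geno, y,
                         snp_ids = paste0("snp", seq_len(cfg$M)))
  list(dataset = ds,
       truth = list(disease_cols = disease_cols, r2 = cfg$r2,
                    model = model))
}

#' Estimate detection power over simulated replicates
#'
#' Power = S / ND, where S counts replicates in which the detector's
#' reported significant sets contain the exact planted disease-locus tuple
#' (the tuple of their LD markers when `r2 < 1`). Per-replicate seeds are
#' derived deterministically from `cfg$seed`.
#'
#' @param detector function taking a [genotype_dataset()] and the truth
#'   record, returning reported K-SNP sets as a data frame with columns
#'   `snp1..snpK` (as produced by [run_stage2()]) or a list of integer
#'   vectors.
#' @param model a [penetrance_model()].
#' @param cfg a [sim_config()]; `n_datasets` replicates are generated.
#' @return A list of class `power_result` with `S`, `ND`, `power` and the
#'   per-replicate success vector.
#' @export
estimate_power <- function(detector, model, cfg) {
  stopifnot(is.function(detector), inherits(cfg, "sim_config"),
            cfg$n_datasets >= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_datasets)
  hits <- logical(cfg$n_datasets)
  for (r in seq_len(cfg$n_datasets)) {
    cfg_r <- cfg
    cfg_r$seed <- rep_seeds[r]
    sim <- sample_case_control(model, cfg_r)
    found <- detector(sim$dataset, sim$truth)
    if (inherits(found, "episcreen_result")) found <- found$interactions
    truth <- sort(sim$truth$disease_cols)
    kk <- length(truth)
    sets <- if (is.data.frame(found)) {
      idc <- paste0("id", seq_len(kk))
      sic <- paste0("snp", seq_len(kk))
      if (nrow(found) == 0L) {
        list()
      } else if (all(idc %in% names(found))) {
        # id columns survive QC column shifts: map back to input positions
        lapply(seq_len(nrow(found)), function(i)
          sort(match(unlist(found[i, idc]), sim$dataset$snp_ids)))
      } else if (all(sic %in% names(found))) {
        lapply(seq_len(nrow(found)),
               function(i) sort(as.integer(unlist(found[i, sic]))))
      } else list()
    } else {
      lapply(found, function(s) sort(as.integer(s)))
    }
    hits[r] <- any(vapply(sets, function(s)
      length(s) == length(truth) && all(s == truth), logical(1)))
  }
  structure(list(S = sum(hits), ND = cfg$n_datasets,
                 power = mean(hits), hits = hits),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power = %d/%d = %.3f\n", x$S, x$ND, x$power))
  invisible(x)
}
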