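test_that("Hardy-Weinberg sampling matches its genotype distribution", {
  expect_equal(genotypes_hwe(0, 50), rep(0L, 50))
  set.seed(301)
  g <- genotypes_hwe(0.5, 1e5)
  gof <- chisq.test(tabulate(g + 1L, 3L), p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.01)
  # mean genotype ~ 2 maf within 3 standard errors
  se <- sqrt(2 * 0.5 * 0.5 / 1e5)
  expect_lt(abs(mean(g) - 1), 3 * se)
})

test_that("marginal effect size is the heterozygote odds ratio minus one", {
  # k = 1 table with odds(P_Aa) = 1.2 odds(P_AA) -> lambda = 0.2 exactly
  o0 <- 0.1 / 0.9
  f1 <- 1.2 * o0 / (1 + 1.2 * o0)
  m <- penetrance_model("custom_table", table = array(c(0.1, f1, 0.3), 3),
                        mafs = 0.3)
  expect_equal(marginal_effect_size(m, 1), 0.2, tolerance = 1e-12)
  # equal marginal penetrances -> lambda = 0
  m0 <- penetrance_model("custom_table",
                         table = array(rep(0.2, 27), rep(3, 3)),
                         mafs = rep(0.3, 3))
  expect_equal(marginal_effect_size(m0, 2), 0)
})

test_that("threshold-family marginals match a hand summation", {
  m <- penetrance_model("threshold3", maf = 0.25, lambda = 0.3,
                        prevalence = 0.01)
  pr <- hwe_probs_test(0.25)
  # P_AA and P_Aa by explicit summation over the 9 co-locus combinations
  hand <- sapply(0:1, function(g1) {
    tot <- 0
    for (g2 in 0:2) for (g3 in 0:2)
      tot <- tot + pr[g2 + 1] * pr[g3 + 1] * m$table[g1 + 1, g2 + 1, g3 + 1]
    tot
  })
  expect_equal(unname(m$marginal_penetrances[1, 1:2]), hand,
               tolerance = 1e-12)
  odds <- function(p) p / (1 - p)
  expect_equal(odds(hand[2]) / odds(hand[1]) - 1, 0.3, tolerance = 1e-6)
})

test_that("calibrated families round-trip their targets", {
  for (maf in c(0.1, 0.2, 0.4)) {
    m1 <- penetrance_model("multiplicative3", maf = maf, lambda = 0.2,
                           prevalence = 0.01)
    for (i in 1:3)
      expect_equal(marginal_effect_size(m1, i), 0.2, tolerance = 1e-6)
    expect_equal(m1$prevalence, 0.01, tolerance = 1e-8)
    m2 <- penetrance_model("threshold3", maf = maf, lambda = 0.3,
                           prevalence = 0.01)
    for (i in 1:3)
      expect_equal(marginal_effect_size(m2, i), 0.3, tolerance = 1e-6)
  }
  # lambda target 0 collapses to a constant-penetrance (null) model
  m0 <- penetrance_model("multiplicative3", maf = 0.3, lambda = 0,
                         prevalence = 0.01)
  expect_lt(m0$h2, 1e-10)
  expect_lt(max(abs(m0$lambdas)), 1e-8)
})

test_that("pure-epistasis models have zero marginals and the target h2", {
  for (h2 in c(0.05, 0.2, 0.4)) {
    m <- penetrance_model("pure3", h2 = h2)
    expect_lt(max(abs(m$lambdas)), 1e-10)
    expect_equal(m$h2, h2, tolerance = 1e-6)
    expect_true(all(abs(m$marginal_penetrances - m$prevalence) < 1e-12))
  }
  # feasible user-supplied prevalence is honored
  mfix <- penetrance_model("pure3", h2 = 0.05, prevalence = 0.1)
  expect_equal(mfix$prevalence, 0.1, tolerance = 1e-12)
  expect_equal(mfix$h2, 0.05, tolerance = 1e-10)
  # infeasible combination reports the feasible range
  expect_error(penetrance_model("pure3", h2 = 0.4, prevalence = 0.05),
               "unattainable")
})

test_that("stored annotations agree with independent recomputation", {
  models <- list(
    penetrance_model("multiplicative3", maf = 0.2, lambda = 0.2),
    penetrance_model("threshold3", maf = 0.4, lambda = 0.3),
    penetrance_model("pure3", h2 = 0.2))
  for (m in models) {
    pr_loc <- lapply(m$mafs, hwe_probs_test)
    g <- as.matrix(expand.grid(0:2, 0:2, 0:2))
    joint <- pr_loc[[1]][g[, 1] + 1] * pr_loc[[2]][g[, 2] + 1] *
      pr_loc[[3]][g[, 3] + 1]
    f <- mapply(function(a, b, c) m$table[a + 1, b + 1, c + 1],
                g[, 1], g[, 2], g[, 3])
    prev <- sum(joint * f)
    expect_equal(m$prevalence, prev, tolerance = 1e-8)
    h2 <- sum(joint * (f - prev)^2) / (prev * (1 - prev))
    expect_equal(m$h2, h2, tolerance = 1e-8)
  }
})

test_that("case-control sampling hits its quota and calibration", {
  m0 <- penetrance_model("custom_table",
                         table = array(rep(0.3, 27), rep(3, 3)),
                         mafs = rep(0.3, 3))
  cfg <- sim_config(M = 6, n_case = 150, n_control = 250, seed = 302)
  sim <- sample_case_control(m0, cfg)
  expect_equal(sim$dataset$n_case, 150L)
  expect_equal(sim$dataset$n_control, 250L)
  expect_equal(length(sim$truth$disease_cols), 3L)
  # constant penetrance: single-locus tests at disease loci are null
  set.seed(303)
  pvals <- replicate(100, {
    s <- sample_case_control(m0, sim_config(M = 4, n_case = 100,
                                            n_control = 100))
    bits <- bit_encode(s$dataset)
    j <- s$truth$disease_cols[1]
    cnt <- episcreen:::single_locus_counts(bits)
    chi_squared_test(cbind(cnt$case[, j], cnt$control[, j]))$p_value
  })
  rej <- mean(pvals < 0.05)
  expect_gte(rej, 0.005)
  expect_lte(rej, 0.12)
})

test_that("a strong pure-epistasis signal crosses the Bonferroni bar", {
  mp <- penetrance_model("pure3", h2 = 0.4)
  thr <- critical_statistic(bonferroni_level(0.05, 100, 3), 26)
  set.seed(304)
  hits <- replicate(30, {
    s <- sample_case_control(mp, sim_config(M = 10, n_case = 200,
                                            n_control = 200))
    bits <- bit_encode(s$dataset)
    tab <- contingency_table(bits, s$truth$disease_cols)
    chi_squared_test(tab)$statistic > thr
  })
  expect_gte(mean(hits), 0.9)
})

test_that("LD markers reproduce the target r-squared", {
  set.seed(305)
  n <- 1e5
  maf <- 0.5
  h1 <- rbinom(n, 1, maf)
  h2 <- rbinom(n, 1, maf)
  mk <- ld_marker(h1, h2, maf, r2 = 0.7)
  emp <- cor(c(h1, h2), c(mk$m1, mk$m2))^2
  expect_lt(abs(emp - 0.7), 0.02)
  # r2 = 1: the marker is the locus
  mk1 <- ld_marker(h1, h2, maf, r2 = 1)
  expect_identical(mk1$genotype, as.integer(h1 + h2))
  # near-independence limit
  mk0 <- ld_marker(h1, h2, maf, r2 = 1e-4)
  expect_lt(cor(c(h1, h2), c(mk0$m1, mk0$m2))^2, 0.01)
})

test_that("r2 < 1 genotypes markers, not the disease loci", {
  mp <- penetrance_model("pure3", h2 = 0.4)
  cfg <- sim_config(M = 5, n_case = 300, n_control = 300, seed = 306,
                    r2 = 0.7)
  sim <- sample_case_control(mp, cfg)
  expect_equal(sim$truth$r2, 0.7)
  # the marker triple still carries (attenuated) signal
  bits <- bit_encode(sim$dataset)
  tab <- contingency_table(bits, sim$truth$disease_cols)
  expect_gt(chi_squared_test(tab)$statistic, 26)
})

test_that("power estimation scores exact-tuple recovery", {
  mp <- penetrance_model("pure3", h2 = 0.2)
  cfg <- sim_config(M = 5, n_case = 30, n_control = 30, seed = 307,
                    n_datasets = 6)
  oracle_det <- function(ds, truth) list(truth$disease_cols)
  expect_equal(estimate_power(oracle_det, mp, cfg)$power, 1)
  null_det <- function(ds, truth) list()
  expect_equal(estimate_power(null_det, mp, cfg)$power, 0)
  # data-frame detectors are scored identically
  df_det <- function(ds, truth) {
    s <- sort(truth$disease_cols)
    data.frame(snp1 = s[1], snp2 = s[2], snp3 = s[3])
  }
  pw <- estimate_power(df_det, mp, cfg)
  expect_equal(pw$S, 6L)
  expect_equal(pw$ND, 6L)
})

test_that("power grows with heritability and sample size", {
  thr <- critical_statistic(bonferroni_level(0.05, 100, 3), 26)
  direct_det <- function(ds, truth) {
    bits <- bit_encode(ds)
    tab <- contingency_table(bits, truth$disease_cols)
    if (chi_squared_test(tab)$statistic > thr) list(truth$disease_cols)
    else list()
  }
  # fixed prevalence keeps the low class strictly positive so detection is
  # genuinely graded in h2 and N rather than trivially saturated
  pw <- function(h2, n) {
    m <- penetrance_model("pure3", h2 = h2, prevalence = 0.3)
    estimate_power(direct_det, m,
                   sim_config(M = 5, n_case = n, n_control = n, seed = 308,
                              n_datasets = 25))$power
  }
  p_h <- c(pw(0.025, 100), pw(0.1, 100), pw(0.3, 100))
  expect_true(all(diff(p_h) >= 0))
  expect_gt(p_h[3], p_h[1])
  p_n <- c(pw(0.1, 50), pw(0.1, 100), pw(0.1, 250))
  expect_true(all(diff(p_n) >= 0))
  expect_gt(p_n[3], p_n[1])
})
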