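test_that("TSV round-trip preserves genotypes, phenotype and ids", {
  tsv <- file.path(tempdir(), "mini.tsv")
  writeLines(c("sample_id\tphenotype\trs1\trs2",
               "s1\t0\t0\t2",
               "s2\t0\t1\tNA",
               "s3\t1\t2\t1",
               "s4\t1\t0\t0"), tsv)
  ds <- read_genotypes(tsv, "tsv")
  expect_equal(nrow(ds$genotypes), 4L)
  expect_equal(ds$snp_ids, c("rs1", "rs2"))
  expect_equal(ds$genotypes[, 1L], c(0L, 1L, 2L, 0L))
  expect_equal(ds$genotypes[, 2L], c(2L, NA, 1L, 0L))
  expect_equal(ds$phenotype, c(0L, 0L, 1L, 1L))
  expect_equal(ds$n_case, 2L)
  out <- file.path(tempdir(), "mini2.tsv")
  write_genotype_tsv(ds, out)
  expect_identical(readLines(tsv), readLines(out))
})

test_that("TSV parse errors carry the offending line number", {
  tsv <- file.path(tempdir(), "bad.tsv")
  writeLines(c("sample_id\tphenotype\trs1", "s1\t1\t0", "s2\t1"), tsv)
  expect_error(read_genotypes(tsv, "tsv"), "line 3")
  writeLines(c("sample_id\tphenotype\trs1", "s1\t1\t7"), tsv)
  expect_error(read_genotypes(tsv, "tsv"), "line 2")
})

test_that("PED genotypes become minor-allele counts; '0 0' is missing", {
  # rs1: alleles A A / A G / G G / A A -> G is minor (3 of 8) -> codes 0,1,2,0
  ped <- c("F1 I1 0 0 1 1  A A  C C",
           "F2 I2 0 0 1 2  A G  C C",
           "F3 I3 0 0 1 2  G G  0 0",
           "F4 I4 0 0 1 1  A A  C T")
  map <- c("1 rs1 0 100", "1 rs2 0 200")
  pf <- file.path(tempdir(), "t.ped")
  mf <- file.path(tempdir(), "t.map")
  writeLines(ped, pf); writeLines(map, mf)
  ds <- read_genotypes(pf, "pedmap")
  expect_equal(ds$snp_ids, c("rs1", "rs2"))
  expect_equal(ds$genotypes[, 1L], c(0L, 1L, 2L, 0L))
  expect_equal(ds$genotypes[, 2L], c(0L, 0L, NA, 1L))  # T minor at rs2
  expect_equal(ds$phenotype, c(0L, 1L, 1L, 0L))        # 1/2 -> 0/1
})

test_that("non-biallelic SNPs are rejected with their id", {
  ped <- c("F1 I1 0 0 1 1  A A",
           "F2 I2 0 0 1 2  C G")
  map <- "1 rsX 0 1"
  pf <- file.path(tempdir(), "nb.ped")
  writeLines(ped, pf)
  writeLines(map, file.path(tempdir(), "nb.map"))
  expect_error(read_genotypes(pf, "pedmap"), "rsX")
})

test_that("HWE goodness of fit matches hand computation and conventions", {
  # exact HWE at p = 0.3, N = 1000: statistic 0, p-value 1
  expect_equal(hwe_pvalue(c(490, 420, 90)), 1)
  # (500, 0, 500): p-hat = 0.5, expected (250, 500, 250),
  # statistic = 250^2/250 + 500^2/500 + 250^2/250 = 1000
  expect_equal(hwe_pvalue(c(500, 0, 500)),
               pchisq(1000, df = 1, lower.tail = FALSE))
  # monomorphic convention
  expect_equal(hwe_pvalue(c(10, 0, 0)), 1)
  expect_equal(hwe_pvalue(c(0, 0, 7)), 1)
  expect_error(hwe_pvalue(c(0, 0, 0)))
})

test_that("quality control applies the four rules in order and reports", {
  set.seed(11)
  ds <- random_dataset(20, 5, maf = rep(0.3, 5))
  # clean data: nothing triggers
  qc <- quality_control(ds)
  expect_equal(nrow(qc$report), 0L)
  expect_equal(dim(qc$dataset$genotypes), dim(ds$genotypes))

  # SNP with 90% call rate is removed under the call-rate rule; with 60
  # SNPs the two affected samples keep call rate 59/60 > 0.98 and survive
  # the preceding sample filter
  set.seed(13)
  dsw <- random_dataset(20, 60, maf = rep(0.3, 60))
  g <- dsw$genotypes
  g[1:2, 3] <- NA  # 18/20 = 0.90 < 0.95
  ds2 <- genotype_dataset(g, dsw$phenotype, snp_ids = dsw$snp_ids)
  qc2 <- quality_control(ds2)
  expect_true("snp3" %in% qc2$report$entity)
  expect_equal(qc2$report$rule[qc2$report$entity == "snp3"], "snp_call_rate")
  expect_false("snp3" %in% qc2$dataset$snp_ids)

  # SNP at MAF 0.05 is removed under the MAF rule
  set.seed(12)
  g3 <- cbind(ds$genotypes, rbinom(20, 2, 0.05))
  while (mean(g3[, 6]) / 2 >= 0.1) g3[, 6] <- rbinom(20, 2, 0.02)
  ds3 <- genotype_dataset(g3, ds$phenotype)
  qc3 <- quality_control(ds3)
  expect_true(any(qc3$report$rule == "maf"))
  expect_false("snp6" %in% qc3$dataset$snp_ids)

  # low-call-rate sample removed first
  g4 <- ds$genotypes
  g4[7, 1:2] <- NA  # 3/5 = 0.6 < 0.98
  ds4 <- genotype_dataset(g4, ds$phenotype)
  qc4 <- quality_control(ds4)
  expect_true(any(qc4$report$entity_type == "sample"))
  expect_equal(nrow(qc4$dataset$genotypes), 19L)
})

test_that("quality control is idempotent", {
  set.seed(21)
  g <- sapply(1:8, function(j) rbinom(60, 2, runif(1, 0.05, 0.5)))
  g[sample(length(g), 30)] <- NA
  ds <- genotype_dataset(g, rep(0:1, 30))
  qc1 <- quality_control(ds)
  qc2 <- quality_control(qc1$dataset)
  expect_equal(nrow(qc2$report), 0L)
  expect_identical(qc2$dataset$genotypes, qc1$dataset$genotypes)
})

test_that("all SNPs removed raises an explicit error", {
  set.seed(31)
  g <- matrix(rbinom(40, 2, 0.02), 20, 2)  # MAF far below 0.1
  ds <- genotype_dataset(g, rep(0:1, 10))
  expect_error(quality_control(ds), "all SNPs")
})

test_that("bit encoding reproduces per-class genotype membership", {
  # case genotypes [0, 0, 1, 2] -> bitsets 1100, 0010, 0001
  g <- matrix(c(0L, 0L, 1L, 2L, NA, 1L), ncol = 1)
  ds <- genotype_dataset(g, c(1, 1, 1, 1, 0, 0))
  bits <- bit_encode(ds)
  case_bits <- lapply(1:3, function(gg)
    as.integer(rawToBits(bits$case[, gg, 1]))[1:4])
  expect_equal(case_bits[[1]], c(1L, 1L, 0L, 0L))
  expect_equal(case_bits[[2]], c(0L, 0L, 1L, 0L))
  expect_equal(case_bits[[3]], c(0L, 0L, 0L, 1L))
  # missing genotype (control sample 1) is 0 in all three control bitsets
  ctrl_first_bit <- sapply(1:3, function(gg)
    as.integer(rawToBits(bits$control[, gg, 1]))[1])
  expect_equal(ctrl_first_bit, c(0L, 0L, 0L))
})

test_that("bitset popcounts equal naive genotype tallies", {
  set.seed(41)
  g <- matrix(sample(c(0:2, NA), 50 * 3, TRUE, prob = c(.3, .3, .3, .1)),
              50, 3)
  ds <- genotype_dataset(g, rep(0:1, 25))
  bits <- bit_encode(ds)
  cnt <- episcreen:::single_locus_counts(bits)
  for (j in 1:3) {
    for (gg in 0:2) {
      expect_equal(cnt$case[gg + 1, j],
                   sum(g[ds$phenotype == 1, j] == gg, na.rm = TRUE))
      expect_equal(cnt$control[gg + 1, j],
                   sum(g[ds$phenotype == 0, j] == gg, na.rm = TRUE))
    }
  }
})

test_that("contingency tables equal brute-force counts (k = 1..4)", {
  # concentrated case: every sample genotype 0 at both SNPs
  g0 <- matrix(0L, 10, 2)
  ds0 <- genotype_dataset(g0, rep(0:1, 5))
  tab0 <- contingency_table(bit_encode(ds0), c(1, 2))
  expect_equal(unname(tab0$counts[1, ]), c(5L, 5L))
  expect_equal(sum(tab0$counts[-1, ]), 0L)

  # explicit 8-sample fixture against nested-loop counting
  g8 <- matrix(c(0, 1, 2, 0, 1, 2, 0, 1,
                 2, 2, 1, 0, 0, 1, 2, 0), 8, 2)
  ds8 <- genotype_dataset(g8, c(1, 1, 1, 1, 0, 0, 0, 0))
  tab8 <- contingency_table(bit_encode(ds8), c(1, 2))
  expect_equal(unname(tab8$counts),
               unname(naive_contingency(g8, ds8$phenotype, c(1, 2))))

  # all triples of a random 200 x 5 dataset
  set.seed(51)
  ds <- random_dataset(200, 5)
  bits <- bit_encode(ds)
  for (tr in utils::combn(5, 3, simplify = FALSE)) {
    expect_equal(
      unname(contingency_table(bits, tr)$counts),
      unname(naive_contingency(ds$genotypes, ds$phenotype, tr)))
  }

  # property: random data with missingness, k in 1..4
  set.seed(52)
  for (k in 1:4) {
    g <- matrix(sample(c(0:2, NA), 80 * 6, TRUE, prob = c(.3, .3, .3, .1)),
                80, 6)
    ds <- genotype_dataset(g, sample(rep(0:1, 40)))
    bits <- bit_encode(ds)
    snps <- sample(6, k)
    expect_equal(unname(contingency_table(bits, snps)$counts),
                 unname(naive_contingency(g, ds$phenotype, snps)))
  }
})

test_that("complete-data tables have total N and class margins", {
  set.seed(61)
  ds <- random_dataset(120, 6)
  bits <- bit_encode(ds)
  for (k in 1:4) {
    tab <- contingency_table(bits, seq_len(k))
    expect_equal(tab$N, 120L)
    expect_equal(unname(tab$col_margins),
                 c(ds$n_case, ds$n_control))
  }
  expect_error(contingency_table(bits, c(2, 2)), "duplicate")
  expect_error(contingency_table(bits, c(1, 99)), "range")
})
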