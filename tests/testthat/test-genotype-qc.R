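test_that("MAF computation and classification follow the stated boundaries", {
  expect_equal(compute_maf(c(0, 0, 1, 2)), 0.375)
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_equal(compute_maf(c(2, 2, NA, 1)), 1 / 6)
  expect_error(compute_maf(c(NA, NA)), "missing")

  expect_identical(as.character(classify_maf(c(0, 0.0499999, 0.05, 0.0999, 0.1, 0.5))),
                   c("monomorphic", "rare", "intermediate", "intermediate",
                     "common", "common"))
  expect_error(classify_maf(0.6), "0.5")
  expect_error(classify_maf(-0.1), "0")
})

test_that("the exact HWE test matches full Levene-Haldane enumeration", {
  # monomorphic: a single attainable configuration
  expect_equal(hwe_exact_test(20, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 35), 1)

  # balanced table at the modal heterozygote count
  expect_equal(hwe_exact_test(25, 50, 25), hwe_p_oracle(25, 50, 25),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-12)

  # extreme heterozygote deficit fails the 1e-6 screen
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)

  # random spot tables against the recurrence oracle
  set.seed(13)
  for (k in 1:50) {
    n <- sample(5:120, 1)
    n1 <- sample(0:n, 1)
    hs <- seq.int(n1 %% 2L, n1, by = 2L)
    h <- sample(hs, 1)
    tab <- c((n1 - h) / 2, h, n - (n1 + h) / 2)
    expect_equal(hwe_exact_test(tab[1], tab[2], tab[3]),
                 hwe_p_oracle(tab[1], tab[2], tab[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
})

test_that("the exact HWE test has clean null behavior at herd scale", {
  # type-I: null simulation at n = 96, MAF 0.3 -- the 1e-6 screen fires never
  # (or once in a blue moon); empirically zero here under a fixed seed
  set.seed(29)
  g <- matrix(rbinom(96 * 10000, 2, 0.3), 96, 10000)
  p <- apply(g, 2, function(x) hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0)))
  expect_true(all(p > 0 & p <= 1))
  expect_identical(sum(p < 1e-6), 0L)
})

test_that("sample heterozygosity and the 3-SD rule flag exactly the planted outlier", {
  expect_equal(sample_heterozygosity(c(1, 1, 1, NA)), 1)
  expect_error(sample_heterozygosity(c(NA_integer_, NA_integer_)), "usable")

  # identical rates: SD = 0, nothing flagged
  expect_identical(flag_het_outliers(rep(0.3, 10)), integer(0))

  set.seed(17)
  rates <- c(rnorm(95, 0.3, 0.005), 0.9)
  expect_identical(flag_het_outliers(rates), 96L)
})

test_that("genotype PCA standardizes by allele frequency and matches the svd conventions", {
  p <- genotype_sim_params(n_samples = 60, n_snps = 400, missing_rate = 0.02)
  gm <- generate_genotype_matrix(p, seed = 21)$genotypes
  pca <- genotype_pca(gm, k = 5)
  expect_true(all(diff(pca$eigenvalues) <= 1e-9))

  # scores' Gram matrix diagonal equals eigenvalues * (n - 1)
  gram <- crossprod(pca$scores)
  expect_equal(diag(gram), pca$eigenvalues * (60 - 1), tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores are orthogonal
  off <- gram - diag(diag(gram))
  expect_lt(max(abs(off)), 1e-6)

  # rank deficiency: two distinct rows duplicated -> one dominant component
  # and scores collapsing to two clusters
  base <- rbind(rep(0L, 50), rep(2L, 50))
  dup <- toy_genotypes(base[rep(1:2, each = 15), ])
  dup$calls[1, 1] <- 1L  # break exact zero variance of the first column
  pca2 <- genotype_pca(dup, k = 2)
  expect_gt(pca2$eigenvalues[1] / sum(pca2$eigenvalues), 0.9)
  expect_lt(max(tapply(pca2$scores[, 1], rep(1:2, each = 15), stats::sd)), 0.2)

  expect_error(genotype_pca(toy_genotypes(matrix(1L, 4, 5)), k = 2), "variance")
})

test_that("run_qc removes exactly the planted violations, in the documented order", {
  p <- genotype_sim_params(n_samples = 96, n_snps = 1000, maf_low = 0.15,
                           missing_rate = 0.01, n_hwe_violating = 5,
                           n_het_outliers = 2, n_low_call_samples = 2,
                           n_low_call_snps = 3, n_rare_snps = 4)
  sim <- generate_genotype_matrix(p, seed = 33)
  res <- run_qc(sim$genotypes)
  rep_ <- res$report
  tru <- sim$truth
  ids <- sim$genotypes$map$id
  expect_setequal(rep_$removed$samples_call_rate,
                  sim$genotypes$samples[tru$low_call_samples])
  expect_setequal(rep_$removed$snps_call_rate, ids[tru$low_call_snps])
  expect_setequal(rep_$removed$snps_maf, ids[tru$rare_snps])
  expect_setequal(rep_$removed$snps_hwe, ids[tru$hwe_violating_snps])
  expect_setequal(rep_$removed$samples_heterozygosity,
                  sim$genotypes$samples[tru$het_outlier_samples])

  # conservation: removed + surviving = input, per axis
  expect_identical(unname(rep_$surviving["samples"] +
                          length(tru$low_call_samples) + length(tru$het_outlier_samples)),
                   96L)
  expect_identical(unname(rep_$surviving["snps"]) + 5L + 3L + 4L, 1000L)

  # idempotence on this matrix: a second pass removes nothing
  res2 <- run_qc(res$genotypes)
  expect_true(all(res2$report$removed_counts == 0))
  expect_identical(res2$genotypes$calls, res$genotypes$calls)
})

test_that("a clean matrix passes QC untouched and a hand-built toy traces by hand", {
  p <- genotype_sim_params(n_samples = 80, n_snps = 500, maf_low = 0.15,
                           missing_rate = 0.01)
  sim <- generate_genotype_matrix(p, seed = 41)
  res <- run_qc(sim$genotypes)
  expect_true(all(res$report$removed_counts == 0))
  expect_identical(dim(res$genotypes$calls), c(80L, 500L))

  # 6 x 8 toy: sample 6 has 3/8 missing (call rate 0.625); SNP 7 is missing in
  # 2/5 remaining samples (0.6); SNP 8 is monomorphic (MAF 0) -- removals 1/1/1
  calls <- rbind(
    c(0L, 1L, 2L, 1L, 0L, 1L, 1L, 0L),
    c(1L, 0L, 1L, 2L, 1L, 0L, NA, 0L),
    c(2L, 1L, 0L, 1L, 2L, 1L, 1L, 0L),
    c(1L, 2L, 1L, 0L, 1L, 2L, NA, 0L),
    c(0L, 1L, 2L, 1L, 0L, 1L, 1L, 0L),
    c(NA, NA, NA, 1L, 0L, 1L, 1L, 0L))
  toy <- toy_genotypes(calls)
  res2 <- run_qc(toy, qc_thresholds(sample_call = 0.7, snp_call = 0.7))
  expect_identical(res2$report$removed$samples_call_rate, "an06")
  expect_identical(res2$report$removed$snps_call_rate, "s07")
  expect_identical(res2$report$removed$snps_maf, "s08")
  expect_identical(unname(res2$report$surviving), c(5L, 6L))

  # fail-fast empties
  allbad <- toy_genotypes(matrix(NA_integer_, 3, 3))
  allbad$calls[1, 1] <- 1L
  expect_error(run_qc(allbad), "empty after QC")
})
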