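test_that("snp_regression matches the lm oracle and handles degenerate inputs", {
  # noiseless fit: y = 2 g exactly
  g <- c(0, 1, 2, 1, 0, 2, 1)
  fit <- snp_regression(2 * g, g)
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_equal(fit$se, 0, tolerance = 1e-12)

  # constant genotype: NA with a reason code, never a silent drop
  fit0 <- snp_regression(rnorm(10), rep(1, 10))
  expect_true(is.na(fit0$beta))
  expect_identical(fit0$reason, "monomorphic-in-tested-set")

  # random instances against lm()/summary.lm, with and without covariates
  set.seed(71)
  for (k in 1:25) {
    n <- sample(10:40, 1)
    g <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (var(g) == 0) next
    y <- 1 + 0.5 * g + rnorm(n)
    covar <- if (k %% 2 == 0) cbind(a = rnorm(n), b = runif(n)) else NULL
    fit <- snp_regression(y, g, covar)
    ref <- if (is.null(covar)) summary(lm(y ~ g))
           else summary(lm(y ~ covar + g))
    row <- nrow(ref$coefficients)
    expect_equal(fit$beta, ref$coefficients[row, 1], tolerance = 1e-10)
    expect_equal(fit$se, ref$coefficients[row, 2], tolerance = 1e-10)
    expect_equal(fit$t, ref$coefficients[row, 3], tolerance = 1e-10)
    expect_equal(fit$p, ref$coefficients[row, 4], tolerance = 1e-10)
  }

  # missing dropped, not imputed
  y <- c(1, 2, 3, 4, 5, 6); g <- c(0, 1, 2, NA, 1, 0)
  expect_identical(snp_regression(y, g)$n_used, 5L)
  expect_error(snp_regression(1:4, c(0, 1, NA, NA)), "usable")
  expect_error(snp_regression(rnorm(10), rbinom(10, 2, 0.5),
                              cbind(1:10, 2 * (1:10))), "rank deficient")
})

test_that("bonferroni_threshold is alpha/m with the documented monotonicity", {
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 100)$threshold, 5e-4)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  ms <- c(10, 100, 1000, 111158)
  th <- vapply(ms, function(m) bonferroni_threshold(0.05, m)$threshold, numeric(1))
  expect_true(all(diff(th) < 0))
  expect_equal(bonferroni_threshold(0.1, 50)$threshold,
               2 * bonferroni_threshold(0.05, 50)$threshold)
})

test_that("qq_data pairs sorted observations with uniform order statistics", {
  m <- 200
  p <- (seq_len(m) - 0.5) / m
  qd <- qq_data(sample(p))
  expect_equal(qd$observed, qd$expected, tolerance = 1e-12)

  qd1 <- qq_data(0.5)
  expect_equal(qd1$expected, -log10(0.5))
  expect_equal(qd1$observed, -log10(0.5))

  expect_error(qq_data(c(0.5, 0)), "position 2")
  expect_error(qq_data(c(0.5, 1.2)), "position 2")

  # uniform draws stay within the 99% Kolmogorov band
  set.seed(5)
  u <- runif(10000)
  qd2 <- qq_data(u)
  ks99 <- 1.628 / sqrt(10000)
  expect_lt(max(abs(sort(u) - (seq_len(10000) - 0.5) / 10000)), ks99)
})

test_that("manhattan_data lays chromosomes end to end", {
  a <- data.frame(CHR = c(1, 1, 2, 2), BP = c(100, 400, 50, 120),
                  P = c(0.1, 0.01, 0.5, 0.2))
  md <- manhattan_data(a)
  expect_equal(md$coord, c(100, 400, 450, 520))
  expect_equal(md$neglog10p, -log10(a$P))
  expect_identical(nrow(md), nrow(a))

  one <- data.frame(CHR = 3, BP = c(10, 20), P = c(0.5, 0.5))
  expect_equal(manhattan_data(one)$coord, c(10, 20))

  bad <- data.frame(CHR = c(1, 1), BP = c(400, 100), P = c(0.1, 0.1))
  expect_error(manhattan_data(bad), "sort")
})

test_that("pearson_correlation matches cor.test and trait_summary matches hand arithmetic", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(90)
  for (k in 1:10) {
    a <- rnorm(30); b <- 0.3 * a + rnorm(30)
    pc <- pearson_correlation(a, b)
    ct <- cor.test(a, b)
    expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(pc$p, ct$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")

  ts <- trait_summary(data.frame(animal_id = c("a", "b"), tr = c(1, 3)))
  expect_equal(ts$mean, 2)
  expect_equal(ts$sem, 1)
  expect_equal(ts$cv_pct, 100 * sqrt(2) / 2)
  expect_equal(c(ts$min, ts$max), c(1, 3))
  const <- trait_summary(data.frame(animal_id = c("a", "b", "c"), tr = c(5, 5, 5)))
  expect_equal(const$sem, 0)
  expect_equal(const$cv_pct, 0)
})

test_that("run_gwas scans every SNP in order and is invariant to row permutation", {
  p <- genotype_sim_params(n_samples = 60, n_snps = 300, missing_rate = 0.02,
                           n_causal = 1, effect_sizes = 10)
  sim <- generate_genotype_matrix(p, seed = 55)
  ph <- generate_phenotypes(sim$genotypes, p, seed = 56)
  scan <- run_gwas(ph$phenotypes, "chest_girth_cm", sim$genotypes)
  expect_s3_class(scan, "gwas_scan")
  expect_identical(scan$SNP, sim$genotypes$map$id)
  expect_true(all(is.na(scan$P) | (scan$P > 0 & scan$P <= 1)))
  expect_equal(attr(scan, "threshold")$threshold, 0.05 / 300)

  # consistent relabeling of phenotype rows changes nothing
  perm <- sample(nrow(ph$phenotypes))
  scan2 <- run_gwas(ph$phenotypes[perm, ], "chest_girth_cm", sim$genotypes)
  expect_equal(scan2$P, scan$P)
  expect_equal(scan2$BETA, scan$BETA)

  # the planted causal SNP is the top hit at this effect size
  causal <- ph$truth$chest_girth_cm$causal_snps
  expect_identical(which.min(scan$P), causal)

  expect_error(run_gwas(data.frame(animal_id = "zz", t = 1), "t", sim$genotypes),
               "overlapping")
  expect_error(run_gwas(ph$phenotypes, "no_such_trait", sim$genotypes), "trait")

  # plot methods return their data invisibly on a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off(), add = TRUE)
  md <- plot(scan, type = "manhattan")
  qd <- plot(scan, type = "qq")
  expect_identical(nrow(md), sum(is.finite(scan$P)))
  expect_identical(nrow(qd), sum(is.finite(scan$P)))
  expect_output(print(scan), "gwas_scan")
  expect_output(print(summary(scan)), "Bonferroni")
})

test_that("association tables and pipeline TSVs use the PLINK-style header", {
  p <- genotype_sim_params(n_samples = 30, n_snps = 20, missing_rate = 0)
  sim <- generate_genotype_matrix(p, seed = 77)
  ph <- generate_phenotypes(sim$genotypes, p, seed = 78)
  scan <- run_gwas(ph$phenotypes, "chest_width_cm", sim$genotypes)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_assoc_tsv(scan, f)
  expect_identical(readLines(f, n = 1),
                   "CHR\tSNP\tBP\tA1\tNMISS\tBETA\tSE\tSTAT\tP")
})

test_that("planted-QTL detection power is nondecreasing in effect size and sample size", {
  # 3 x 3 grid: detection rate of the causal SNP at the Bonferroni cut
  rate <- matrix(0, 3, 3, dimnames = list(beta = c(2, 5, 9), n = c(48, 96, 192)))
  panel <- data.frame(trait = "chest_girth_cm", mean = 217.1, cv = 2.5)
  for (bi in seq_along(c(2, 5, 9))) for (ni in seq_along(c(48, 96, 192))) {
    b <- c(2, 5, 9)[bi]; n <- c(48, 96, 192)[ni]
    det <- 0
    for (rep_ in 1:8) {
      pq <- genotype_sim_params(n_samples = n, n_snps = 400, missing_rate = 0,
                                n_causal = 1, effect_sizes = b)
      simq <- generate_genotype_matrix(pq, seed = 100 * bi + 10 * ni + rep_)
      phq <- generate_phenotypes(simq$genotypes, pq, panel,
                                 seed = 7000 + 100 * bi + 10 * ni + rep_)
      scanq <- run_gwas(phq$phenotypes, "chest_girth_cm", simq$genotypes)
      cut <- attr(scanq, "threshold")$threshold
      if (scanq$P[phq$truth$chest_girth_cm$causal_snps] < cut) det <- det + 1
    }
    rate[bi, ni] <- det / 8
  }
  expect_true(all(apply(rate, 2, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(rate, 1, function(x) all(diff(x) >= 0))))
  expect_gt(rate[3, 3], 0.9)
})
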