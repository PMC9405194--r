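# SNP and sample quality control: call rates, minor allele frequency, the
# exact Hardy-Weinberg test, heterozygosity outliers, and a PCA
# stratification check. Filter order is fixed: (1) sample call rate,
# (2) SNP call rate, (3) MAF, (4) HWE, (5) heterozygosity outliers.

#' Minor allele frequency of one SNP
#'
#' `min(f, 1 - f)` where `f` is the A1 allele frequency over non-missing
#' calls; always in \[0, 0.5\]. An all-missing SNP is an error, distinct from
#' a monomorphic one (MAF 0).
#'
#' @param calls vector of genotype calls in `{0, 1, 2, NA}`.
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(calls) {
  g <- calls[!is.na(calls)]
  if (length(g) == 0L) stop("cannot compute MAF: all calls are missing")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Classify a minor allele frequency
#'
#' Categories: monomorphic (MAF = 0), rare (0 < MAF < 0.05), intermediate
#' (0.05 <= MAF < 0.1), common (0.1 <= MAF <= 0.5). Boundaries are
#' left-closed for the intermediate and common classes.
#'
#' @param maf numeric vector of MAFs in \[0, 0.5\].
#' @return factor with levels monomorphic, rare, intermediate, common.
#' @export
classify_maf <- function(maf) {
  if (any(!is.finite(maf)) || any(maf < 0 | maf > 0.5))
    stop("MAF must lie in [0, 0.5]")
  lv <- c("monomorphic", "rare", "intermediate", "common")
  out <- ifelse(maf == 0, "monomorphic",
         ifelse(maf < 0.05, "rare",
         ifelse(maf < 0.1, "intermediate", "common")))
  factor(out, levels = lv)
}

# log Levene-Haldane probability of h heterozygotes among n_dip diploids
# carrying n1 minor alleles, for every attainable h (same parity as n1)
hwe_log_pmf <- function(n_dip, n1) {
  n2 <- 2L * n_dip - n1
  h <- seq.int(n1 %% 2L, min(n1, n2), by = 2L)
  lp <- h * log(2) + lgamma(n_dip + 1) -
    lgamma((n1 - h) / 2 + 1) - lgamma(h + 1) - lgamma((n2 - h) / 2 + 1) +
    lgamma(n1 + 1) + lgamma(n2 + 1) - lgamma(2 * n_dip + 1)
  list(h = h, lp = lp)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' The exact conditional test: given the observed allele counts, the number
#' of heterozygotes follows the Levene-Haldane distribution, and the p-value
#' is the total probability of all heterozygote counts at most as probable as
#' the observed one (plain two-sided exact test, no mid-p adjustment -- the
#' 1e-6 screening threshold demands true tail mass at n ~ 96).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (homozygous A1, heterozygous,
#'   homozygous A2), total at least 1.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  cnt <- c(n_hom1, n_het, n_hom2)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be nonnegative integers")
  n_dip <- sum(cnt)
  if (n_dip < 1L) stop("at least one genotype is required")
  n1 <- 2L * n_hom1 + n_het
  n1 <- min(n1, 2L * n_dip - n1)   # condition on the minor allele count
  d <- hwe_log_pmf(n_dip, n1)
  pr <- exp(d$lp - max(d$lp))
  pr <- pr / sum(pr)               # normalize: probabilities over attainable h
  p_obs <- pr[match(n_het, d$h)]
  if (is.na(p_obs)) stop("observed heterozygote count is not attainable for these allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' Sample heterozygosity and the 3-SD outlier rule
#'
#' `sample_heterozygosity` is the fraction of heterozygous calls among a
#' sample's non-missing calls. `flag_het_outliers` flags samples whose rate
#' deviates from the mean by more than `sd_limit` population standard
#' deviations (divisor n), the convention used for sample screening.
#'
#' @param calls genotype call vector for one sample.
#' @return heterozygosity rate in \[0, 1\].
#' @export
sample_heterozygosity <- function(calls) {
  g <- calls[!is.na(calls)]
  if (length(g) == 0L) stop("cannot compute heterozygosity: no usable calls")
  mean(g == 1L)
}

#' @rdname sample_heterozygosity
#' @param rates vector of per-sample heterozygosity rates (>= 2 samples).
#' @param sd_limit outlier cut in population SDs.
#' @return `flag_het_outliers`: integer indices of flagged samples.
#' @export
flag_het_outliers <- function(rates, sd_limit = 3) {
  if (length(rates) < 2L) stop("outlier flagging needs at least 2 samples")
  mu <- mean(rates)
  sd_pop <- sqrt(mean((rates - mu)^2))
  which(abs(rates - mu) > sd_limit * sd_pop)
}

#' PCA stratification check on a genotype matrix
#'
#' Columns are centered at twice the estimated allele frequency and scaled by
#' `sqrt(2 p (1 - p))` (the unit-variance standardization under
#' Hardy-Weinberg); missing calls are imputed at the column mean before
#' scaling (zero after centering). Eigenvalues are the variances of the
#' principal components (scores' crossproduct diagonal equals
#' `eigenvalues * (n - 1)`).
#'
#' @param genotypes a [genotype_matrix()] (post-QC).
#' @param k number of components, below `min(n, m)`.
#' @return list with `eigenvalues` (nonincreasing, length k) and `scores`
#'   (n x k matrix, rows named by sample).
#' @export
genotype_pca <- function(genotypes, k = 10L) {
  calls <- genotypes$calls
  n <- nrow(calls); m <- ncol(calls)
  k <- as.integer(k)
  if (k < 1L || k >= min(n, m)) stop("`k` must be in [1, min(n, m) - 1]")
  p <- colMeans(calls, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  if (!any(keep)) stop("genotype matrix has zero variance: PCA is undefined")
  x <- calls[, keep, drop = FALSE]
  p <- p[keep]
  mu <- 2 * p
  sc <- sqrt(2 * p * (1 - p))
  x <- sweep(x, 2L, mu)
  if (anyNA(x)) x[is.na(x)] <- 0
  x <- sweep(x, 2L, sc, "/")
  sv <- svd(x, nu = k, nv = 0)
  if (sv$d[1] < 1e-12) stop("genotype matrix has zero variance: PCA is undefined")
  eig <- (sv$d^2) / (n - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- genotypes$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  list(eigenvalues = eig[seq_len(k)], scores = scores)
}

#' QC thresholds
#'
#' The screening chain keeps samples with call rate at least `sample_call`,
#' SNPs with call rate at least `snp_call`, SNPs with MAF at least `maf`,
#' SNPs with exact Hardy-Weinberg p-value at least `hwe_p`, and drops samples
#' whose heterozygosity deviates more than `het_sd` SDs from the mean.
#' Call-rate comparisons are inclusive ("not lower than").
#'
#' @param sample_call,snp_call minimum call rates in (0, 1].
#' @param maf minimum minor allele frequency.
#' @param hwe_p minimum exact-test p-value.
#' @param het_sd heterozygosity outlier cut in SDs.
#' @return a list of thresholds.
#' @export
qc_thresholds <- function(sample_call = 0.9, snp_call = 0.9, maf = 0.05,
                          hwe_p = 1e-6, het_sd = 3) {
  if (sample_call <= 0 || sample_call > 1 || snp_call <= 0 || snp_call > 1)
    stop("call-rate thresholds must be in (0, 1]")
  if (maf < 0 || maf > 0.5) stop("the MAF threshold must be in [0, 0.5]")
  if (hwe_p <= 0 || hwe_p > 1) stop("the HWE threshold must be in (0, 1]")
  if (het_sd <= 0) stop("het_sd must be positive")
  list(sample_call = sample_call, snp_call = snp_call, maf = maf,
       hwe_p = hwe_p, het_sd = het_sd)
}

#' Run the quality-control chain
#'
#' Applies, in this fixed order: (1) sample call rate, (2) SNP call rate,
#' (3) MAF, (4) exact Hardy-Weinberg test, (5) heterozygosity outliers.
#' Records the removal counts and indices at each step, the MAF class counts
#' of the SNPs entering the MAF step, and a PCA stratification check on the
#' surviving matrix.
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] list.
#' @param pca_k components for the stratification check (trimmed to the
#'   surviving dimensions; set 0 to skip).
#' @return list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (a `qc_report` with per-step removals, thresholds, MAF classes,
#'   and PCA results).
#' @export
run_qc <- function(genotypes, thresholds = qc_thresholds(), pca_k = 10L) {
  gm <- genotypes
  n0 <- nrow(gm$calls); m0 <- ncol(gm$calls)
  removed <- list()

  # (1) sample call rate
  cr_sample <- rowMeans(!is.na(gm$calls))
  drop_s <- which(cr_sample < thresholds$sample_call)
  removed$samples_call_rate <- gm$samples[drop_s]
  if (length(drop_s)) gm <- gm[-drop_s, ]
  if (nrow(gm$calls) == 0L) stop("empty after QC: all samples failed the call-rate filter")

  # (2) SNP call rate
  cr_snp <- colMeans(!is.na(gm$calls))
  drop_g <- which(cr_snp < thresholds$snp_call)
  removed$snps_call_rate <- gm$map$id[drop_g]
  if (length(drop_g)) gm <- gm[, -drop_g]
  if (ncol(gm$calls) == 0L) stop("empty after QC: all SNPs failed the call-rate filter")

  # (3) MAF (classes tallied on the SNPs entering this step)
  maf <- apply(gm$calls, 2L, compute_maf)
  maf_classes <- table(classify_maf(maf))
  drop_g <- which(maf < thresholds$maf)
  removed$snps_maf <- gm$map$id[drop_g]
  if (length(drop_g)) gm <- gm[, -drop_g]
  if (ncol(gm$calls) == 0L) stop("empty after QC: all SNPs failed the MAF filter")

  # (4) exact HWE
  hwe_p <- apply(gm$calls, 2L, function(g) {
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 2L), sum(g == 1L), sum(g == 0L))
  })
  drop_g <- which(hwe_p < thresholds$hwe_p)
  removed$snps_hwe <- gm$map$id[drop_g]
  if (length(drop_g)) gm <- gm[, -drop_g]
  if (ncol(gm$calls) == 0L) stop("empty after QC: all SNPs failed the HWE filter")

  # (5) heterozygosity outliers
  het <- apply(gm$calls, 1L, sample_heterozygosity)
  drop_s <- flag_het_outliers(het, thresholds$het_sd)
  removed$samples_heterozygosity <- gm$samples[drop_s]
  if (length(drop_s)) gm <- gm[-drop_s, ]
  if (nrow(gm$calls) == 0L) stop("empty after QC: all samples failed the heterozygosity filter")

  pca <- NULL
  if (pca_k > 0L) {
    k <- min(as.integer(pca_k), nrow(gm$calls) - 1L, ncol(gm$calls) - 1L)
    pca <- tryCatch(genotype_pca(gm, k), error = function(e) NULL)
  }
  report <- structure(list(
    input = c(samples = n0, snps = m0),
    surviving = c(samples = nrow(gm$calls), snps = ncol(gm$calls)),
    removed = removed,
    removed_counts = vapply(removed, length, integer(1)),
    thresholds = thresholds,
    maf_classes = maf_classes,
    pca = pca), class = "qc_report")
  list(genotypes = gm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input:     %d samples x %d SNPs\n", x$input["samples"], x$input["snps"]))
  steps <- c(samples_call_rate = "sample call rate",
             snps_call_rate = "SNP call rate",
             snps_maf = "MAF",
             snps_hwe = "HWE exact test",
             samples_heterozygosity = "heterozygosity outliers")
  for (nm in names(steps))
    cat(sprintf("  removed by %-24s %d\n", paste0(steps[[nm]], ":"),
                x$removed_counts[[nm]]))
  cat(sprintf("  surviving: %d samples x %d SNPs\n",
              x$surviving["samples"], x$surviving["snps"]))
  cat("  MAF classes at the MAF step:",
      paste(sprintf("%s=%d", names(x$maf_classes), as.integer(x$maf_classes)),
            collapse = " "), "\n")
  if (!is.null(x$pca))
    cat(sprintf("  PCA: %d components, leading eigenvalue %.2f\n",
                length(x$pca$eigenvalues), x$pca$eigenvalues[1]))
  invisible(x)
}

#' Write a QC report and PCA scores as TSV
#'
#' @param report a `qc_report` from [run_qc()].
#' @param report_path,scores_path output paths (`scores_path` optional).
#' @return `report_path` invisibly.
#' @export
write_qc_report <- function(report, report_path, scores_path = NULL) {
  df <- data.frame(
    step = c("input_samples", "input_snps",
             names(report$removed_counts),
             "surviving_samples", "surviving_snps",
             paste0("maf_class_", names(report$maf_classes))),
    count = c(report$input["samples"], report$input["snps"],
              unname(report$removed_counts),
              report$surviving["samples"], report$surviving["snps"],
              as.integer(report$maf_classes)))
  utils::write.table(df, report_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scores_path) && !is.null(report$pca)) {
    sc <- data.frame(animal_id = rownames(report$pca$scores),
                     report$pca$scores, check.names = FALSE)
    utils::write.table(sc, scores_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report_path)
}
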