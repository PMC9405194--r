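# Genotype and phenotype simulation: Binomial(2, p) SNP draws with a
# configurable MAF spectrum, missingness, planted quality-control violations
# (Hardy-Weinberg failures, heterozygosity-outlier samples, low call rates,
# rare SNPs), optional subpopulation structure, and phenotypes from the
# additive model y = mu + sum_j beta_j g_ij + e, e ~ N(0, sigma_e^2).

#' Construct a genotype matrix
#'
#' Genotypes are coded as the count of the A1 (minor by construction at
#' simulation time) allele: 0, 1, 2, or `NA` for a missing call. SNP metadata
#' follow the usual map conventions (autosome label, identifier, bp position,
#' alleles A1/A2).
#'
#' @param calls n x m integer matrix (samples x SNPs), values in
#'   `{0, 1, 2, NA}`.
#' @param map data.frame with columns `chrom`, `id`, `bp`, `a1`, `a2`, one
#'   row per SNP.
#' @param samples character vector of sample IDs.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map, samples) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L, NA_integer_)))
    stop("genotype calls must be 0, 1, 2 or NA")
  need <- c("chrom", "id", "bp", "a1", "a2")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    stop("`map` must be a data.frame with columns chrom, id, bp, a1, a2")
  if (nrow(map) != ncol(calls))
    stop(sprintf("map has %d SNPs but calls has %d columns", nrow(map), ncol(calls)))
  if (length(samples) != nrow(calls))
    stop(sprintf("%d sample IDs for %d call rows", length(samples), nrow(calls)))
  if (any(map$bp < 0)) stop("bp positions must be nonnegative")
  dimnames(calls) <- list(samples, map$id)
  structure(list(calls = calls, map = as.data.frame(map, stringsAsFactors = FALSE),
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d samples x %d SNPs, %.2f%% missing>\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (logical or integer).
#' @param j SNP index.
#' @param ... ignored.
#' @return the subsetted [genotype_matrix()].
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  genotype_matrix(x$calls[i, j, drop = FALSE], x$map[j, , drop = FALSE],
                  x$samples[i])
}

#' Genotype-simulation parameters
#'
#' Defaults emulate a modest beef-cattle genotyping panel at desk scale:
#' 96 animals, 5,000 autosomal SNPs, allele frequencies uniform on
#' \[0.1, 0.5\], 1% missing calls, no planted violations and no structure.
#'
#' @param n_samples,n_snps panel dimensions.
#' @param maf_low,maf_high allele-frequency range in (0, 0.5].
#' @param missing_rate independent per-call missingness probability in
#'   \[0, 1).
#' @param n_causal number of causal SNPs per trait for the phenotype model.
#' @param effect_sizes numeric vector of length `n_causal`, trait units per
#'   A1 allele copy.
#' @param residual_sd residual standard deviation in trait units (used when
#'   trait means/CVs are not supplied to [generate_phenotypes()]).
#' @param n_hwe_violating SNPs planted with ~90% heterozygotes so that the
#'   exact Hardy-Weinberg test fails them at p < 1e-6 for n >= ~90.
#' @param n_het_outliers samples planted with heterozygosity far above the
#'   mean + 3 SD flagging rule.
#' @param n_low_call_samples,n_low_call_snps samples/SNPs planted with 15%
#'   missing calls, below the 90% call-rate threshold.
#' @param n_rare_snps SNPs planted with a single heterozygous call
#'   (MAF = 1/(2n), below any workable MAF threshold).
#' @param n_subpops number of equally sized subpopulations (1 = none).
#' @param fst_like_divergence Balding-Nichols F for subpopulation allele
#'   frequencies (0 = no divergence).
#' @param seed default RNG seed carried with the parameters.
#' @return an object of class `genotype_sim_params`.
#' @export
genotype_sim_params <- function(n_samples = 96, n_snps = 5000,
                                maf_low = 0.1, maf_high = 0.5,
                                missing_rate = 0.01,
                                n_causal = 0, effect_sizes = numeric(0),
                                residual_sd = 1,
                                n_hwe_violating = 0, n_het_outliers = 0,
                                n_low_call_samples = 0, n_low_call_snps = 0,
                                n_rare_snps = 0,
                                n_subpops = 1, fst_like_divergence = 0,
                                seed = 1L) {
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (n_snps < 1) stop("n_snps must be at least 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high)
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (n_causal > n_snps) stop("n_causal cannot exceed n_snps")
  if (length(effect_sizes) != n_causal)
    stop(sprintf("effect_sizes has length %d but n_causal = %d",
                 length(effect_sizes), n_causal))
  if (residual_sd < 0) stop("residual_sd must be nonnegative")
  planted <- n_hwe_violating + n_low_call_snps + n_rare_snps
  if (planted > n_snps) stop("more planted SNP violations than SNPs")
  if (n_het_outliers + n_low_call_samples > n_samples)
    stop("more planted sample violations than samples")
  if (n_subpops < 1) stop("n_subpops must be at least 1")
  if (fst_like_divergence < 0 || fst_like_divergence >= 1)
    stop("fst_like_divergence must be in [0, 1)")
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 maf_low = maf_low, maf_high = maf_high,
                 missing_rate = missing_rate,
                 n_causal = as.integer(n_causal), effect_sizes = effect_sizes,
                 residual_sd = residual_sd,
                 n_hwe_violating = as.integer(n_hwe_violating),
                 n_het_outliers = as.integer(n_het_outliers),
                 n_low_call_samples = as.integer(n_low_call_samples),
                 n_low_call_snps = as.integer(n_low_call_snps),
                 n_rare_snps = as.integer(n_rare_snps),
                 n_subpops = as.integer(n_subpops),
                 fst_like_divergence = fst_like_divergence,
                 seed = as.integer(seed)),
            class = "genotype_sim_params")
}

BOS_TAURUS_AUTOSOMES <- 29L

#' Simulate a genotype matrix with planted violations
#'
#' Non-planted SNPs are Binomial(2, p) draws with p ~ Uniform(maf_low,
#' maf_high); under subpopulation structure, each subpopulation draws its own
#' allele frequency from a Balding-Nichols Beta around p. Missing calls occur
#' independently at `missing_rate`. Planted violations (applied after the
#' base draw, each on its own disjoint set of SNPs/samples) are recorded in a
#' truth list of indices:
#' * Hardy-Weinberg violators: each sample is heterozygous with probability
#'   0.9 (far above the 2p(1-p) expectation, failing the exact test at
#'   p < 1e-6 for the panel sizes used here);
#' * heterozygosity-outlier samples: every non-missing call replaced by a
#'   heterozygote with probability 0.9;
#' * low-call-rate samples/SNPs: exactly 15% of calls blanked;
#' * rare SNPs: exactly one heterozygous call (MAF = 1/(2n)).
#'
#' SNPs are assigned to the 29 autosomes round-robin with sorted positions.
#'
#' @param params a [genotype_sim_params()].
#' @param seed RNG seed; defaults to the seed carried in `params`.
#' @return list with `genotypes` (a [genotype_matrix()]), `truth` (planted
#'   index sets and per-sample subpopulation labels), and `allele_freq` (the
#'   generating frequencies).
#' @export
generate_genotype_matrix <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "genotype_sim_params"))
  set.seed(seed)
  n <- params$n_samples; m <- params$n_snps
  p <- stats::runif(m, params$maf_low, params$maf_high)
  if (params$n_subpops > 1 && params$fst_like_divergence > 0) {
    f <- params$fst_like_divergence
    subpop <- rep(seq_len(params$n_subpops), length.out = n)
    subpop <- sort(subpop)
    calls <- matrix(NA_integer_, n, m)
    for (k in seq_len(params$n_subpops)) {
      pk <- stats::rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      rows <- which(subpop == k)
      calls[rows, ] <- stats::rbinom(length(rows) * m, 2L,
                                     rep(pk, each = length(rows)))
    }
  } else {
    subpop <- rep(1L, n)
    calls <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  }

  # disjoint planted SNP sets, then planted sample sets
  pool <- seq_len(m)
  take <- function(k) {
    idx <- utils::head(pool, k)
    pool <<- utils::tail(pool, length(pool) - k)
    idx
  }
  # plant at the end of the panel so the leading SNPs stay a clean background
  pool <- rev(pool)
  hwe_idx <- sort(take(params$n_hwe_violating))
  lowcall_snp_idx <- sort(take(params$n_low_call_snps))
  rare_idx <- sort(take(params$n_rare_snps))
  spool <- rev(seq_len(n))
  stake <- function(k) {
    idx <- utils::head(spool, k)
    spool <<- utils::tail(spool, length(spool) - k)
    sort(idx)
  }
  het_out_idx <- stake(params$n_het_outliers)
  lowcall_sample_idx <- stake(params$n_low_call_samples)

  for (j in hwe_idx) {
    het <- stats::runif(n) < 0.9
    hom <- stats::rbinom(n, 1L, p[j]) * 2L
    calls[, j] <- ifelse(het, 1L, hom)
  }
  for (j in rare_idx) {
    calls[, j] <- 0L
    calls[sample.int(n, 1L), j] <- 1L
  }
  for (i in het_out_idx) {
    het <- stats::runif(m) < 0.9
    calls[i, het] <- 1L
  }

  if (params$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < params$missing_rate, n, m)
    calls[miss] <- NA_integer_
  }
  # low-call planting blanks an exact 15% of entries so the violation is
  # guaranteed, not merely probable
  for (j in lowcall_snp_idx)
    calls[sample.int(n, ceiling(0.15 * n)), j] <- NA_integer_
  for (i in lowcall_sample_idx)
    calls[i, sample.int(m, ceiling(0.15 * m))] <- NA_integer_
  # rare SNPs keep their single het call so the planted MAF is exact
  for (j in rare_idx) {
    calls[, j][is.na(calls[, j])] <- 0L
  }

  chrom <- rep(seq_len(BOS_TAURUS_AUTOSOMES), length.out = m)
  bp <- integer(m)
  for (cc in unique(chrom)) {
    k <- sum(chrom == cc)
    bp[chrom == cc] <- sort(sample.int(1.5e8, k))
  }
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2L * m, replace = TRUE), m, 2L)
  swap <- alleles[, 1] == alleles[, 2]
  alleles[swap, 2] <- ifelse(alleles[swap, 1] == "A", "G", "A")
  map <- data.frame(chrom = chrom,
                    id = sprintf("snp%05d", seq_len(m)),
                    bp = bp, a1 = alleles[, 1], a2 = alleles[, 2],
                    stringsAsFactors = FALSE)
  samples <- sprintf("animal%03d", seq_len(n))
  gm <- genotype_matrix(calls, map, samples)
  list(genotypes = gm,
       truth = list(hwe_violating_snps = hwe_idx,
                    low_call_snps = lowcall_snp_idx,
                    rare_snps = rare_idx,
                    het_outlier_samples = het_out_idx,
                    low_call_samples = lowcall_sample_idx,
                    subpop = subpop),
       allele_freq = p)
}

#' Trait means and coefficients of variation for a beef-cattle herd
#'
#' Default calibration of the phenotype generator: per-trait means and CVs
#' (%) typical of finished Aberdeen-Angus steers (stature ~143 cm, girth
#' ~217 cm, live weight ~615 kg).
#'
#' @return data.frame with columns `trait`, `mean`, `cv` (CV in percent).
#' @export
default_trait_panel <- function() {
  data.frame(
    trait = c("live_weight_kg", "withers_height_cm", "hip_height_cm",
              "chest_width_cm", "chest_girth_cm", "meat_output_pct"),
    mean = c(614.9, 143.1, 146.4, 52.2, 217.1, 60.4),
    cv = c(5.4, 3.9, 3.9, 3.5, 2.5, 2.1),
    stringsAsFactors = FALSE)
}

#' Simulate phenotypes from the additive genetic model
#'
#' For each trait, `y_i = mu + sum_j beta_j g_ij + e_i` with
#' `e_i ~ N(0, sigma_e^2)`. Missing genotypes contribute their SNP's mean
#' dosage. When trait means and CVs are given, `mu` is the trait mean and the
#' residual variance is `(mean * cv/100)^2` minus the variance explained by
#' the planted effects (floored at zero); with `n_causal = 0` the phenotype
#' is pure noise around `mu`. The genetic part is centered so that `mu` stays
#' the trait mean regardless of planted effects. Causal SNPs are drawn per
#' trait (excluding any indices in `exclude_snps`, e.g. planted QC
#' violators); `effect_sizes` are in trait units per A1 allele copy.
#'
#' @param genotypes a [genotype_matrix()].
#' @param params a [genotype_sim_params()] (provides `n_causal`,
#'   `effect_sizes`, `residual_sd`).
#' @param trait_panel data.frame with columns `trait`, `mean`, `cv` (percent,
#'   nonnegative); default [default_trait_panel()]. Pass a single-row panel
#'   for a one-trait table.
#' @param exclude_snps SNP indices never chosen as causal.
#' @param seed RNG seed; defaults to `params$seed + 1`.
#' @return list with `phenotypes` (data.frame keyed by `animal_id`, one
#'   column per trait) and `truth` (per-trait causal SNP indices and effects
#'   in trait units).
#' @export
generate_phenotypes <- function(genotypes, params,
                                trait_panel = default_trait_panel(),
                                exclude_snps = integer(0),
                                seed = params$seed + 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(params, "genotype_sim_params"))
  if (!all(c("trait", "mean", "cv") %in% names(trait_panel)))
    stop("`trait_panel` needs columns trait, mean, cv")
  if (any(trait_panel$cv < 0)) stop("trait CVs must be nonnegative")
  set.seed(seed)
  calls <- genotypes$calls
  n <- nrow(calls); m <- ncol(calls)
  # mean-dosage fill for missing genotypes (generator convention)
  dosage <- calls
  if (anyNA(dosage)) {
    mu_j <- colMeans(dosage, na.rm = TRUE)
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu_j[idx[, 2]]
  }
  eligible <- setdiff(seq_len(m), exclude_snps)
  if (params$n_causal > length(eligible))
    stop("not enough non-excluded SNPs to place the causal effects")
  phen <- data.frame(animal_id = genotypes$samples, stringsAsFactors = FALSE)
  truth <- list()
  for (r in seq_len(nrow(trait_panel))) {
    tr <- trait_panel$trait[r]
    mu <- trait_panel$mean[r]
    sd_t <- mu * trait_panel$cv[r] / 100
    g_part <- numeric(n)
    causal <- integer(0); beta <- numeric(0)
    if (params$n_causal > 0) {
      causal <- sort(sample(eligible, params$n_causal))
      beta <- params$effect_sizes
      g_part <- as.vector(dosage[, causal, drop = FALSE] %*% beta)
      p_j <- colMeans(dosage[, causal, drop = FALSE]) / 2
      var_g <- sum(beta^2 * 2 * p_j * (1 - p_j))
      sigma_e <- sqrt(max(0, sd_t^2 - var_g))
    } else {
      sigma_e <- if (sd_t > 0) sd_t else params$residual_sd
    }
    e <- if (sigma_e > 0) stats::rnorm(n, 0, sigma_e) else numeric(n)
    phen[[tr]] <- mu + g_part - mean(g_part) + e
    truth[[tr]] <- list(causal_snps = causal, beta = beta, mu = mu,
                        sigma_e = sigma_e)
  }
  list(phenotypes = phen, truth = truth)
}
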