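# Per-SNP additive linear-model association scan, Bonferroni threshold,
# Manhattan/QQ data, trait correlations, and summary tables.

#' Single-SNP additive linear regression
#'
#' Ordinary least squares of the trait on `[1, covariates, g]` where `g` is
#' the A1 allele dosage (0/1/2). Samples with a missing trait value or
#' missing genotype are dropped (no dosage imputation at test time). The
#' p-value is two-sided from the t distribution with `n_used - rank` degrees
#' of freedom. A genotype that is constant in the tested set yields an `NA`
#' result with reason code `"monomorphic-in-tested-set"`.
#'
#' @param y numeric trait vector.
#' @param g numeric dosage vector, same length.
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; full rank required).
#' @return list with `beta`, `se`, `t`, `p`, `n_used`, and `reason` (`NA`
#'   unless the SNP was untestable).
#' @export
snp_regression <- function(y, g, covariates = NULL) {
  if (length(y) != length(g)) stop("`y` and `g` must have equal length")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(y))
      stop("`covariates` must have one row per sample")
  }
  ok <- is.finite(y) & is.finite(g)
  if (!is.null(covariates)) ok <- ok & apply(is.finite(covariates), 1L, all)
  n_used <- sum(ok)
  na_result <- function(reason)
    list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
         n_used = n_used, reason = reason)
  if (n_used < 3L) stop(sprintf("only %d usable samples; need at least 3", n_used))
  yy <- y[ok]; gg <- g[ok]
  if (stats::var(gg) == 0) return(na_result("monomorphic-in-tested-set"))
  if (is.null(covariates)) {
    X <- cbind(`(Intercept)` = 1, g = gg)
  } else {
    C <- cbind(`(Intercept)` = 1, covariates[ok, , drop = FALSE])
    if (qr(C)$rank < ncol(C)) stop("covariate matrix is rank deficient")
    X <- cbind(C, g = gg)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) return(na_result("dosage-collinear-with-covariates"))
  df <- n_used - qr_x$rank
  if (df < 1L) return(na_result("no-residual-degrees-of-freedom"))
  coefs <- qr.coef(qr_x, yy)
  res <- yy - X %*% coefs
  rss <- sum(res^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[ncol(X), ncol(X)])
  beta <- coefs[ncol(X)]
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = unname(beta), se = se, t = unname(tval), p = max(p, .Machine$double.xmin),
       n_used = n_used, reason = NA_character_)
}

#' Bonferroni genome-wide threshold
#'
#' `threshold = alpha / m` where `m` is the number of SNPs tested after QC.
#' Associations with p-value strictly below the threshold are declared
#' significant.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests, at least 1.
#' @return list of class `scan_threshold` with `alpha`, `m`, `threshold`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.finite(m) || m < 1) stop("m must be at least 1")
  structure(list(alpha = alpha, m = as.integer(m), threshold = alpha / m),
            class = "scan_threshold")
}

#' @export
print.scan_threshold <- function(x, ...) {
  cat(sprintf("<scan_threshold: alpha = %g over m = %d tests -> p < %.4g>\n",
              x$alpha, x$m, x$threshold))
  invisible(x)
}

#' Genome-wide association scan for one trait
#'
#' Joins the phenotype table to the genotype matrix on `animal_id` and runs
#' [snp_regression()] for every SNP, in matrix order. Covariates may name
#' other phenotype columns and/or request leading principal-component scores
#' (`pca = k` entries of a [genotype_pca()] result).
#'
#' @param phenotypes data.frame with `animal_id` and trait columns.
#' @param trait name of the trait column to scan.
#' @param genotypes post-QC [genotype_matrix()].
#' @param covariates optional character vector of phenotype column names used
#'   as covariates.
#' @param pca_scores optional score matrix (rows named by sample) whose
#'   columns are appended as covariates.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return a `gwas_scan`: data.frame with PLINK-style columns `CHR SNP BP A1
#'   NMISS BETA SE STAT P` plus a `REASON` code for untestable SNPs, and
#'   attributes `trait` and `threshold`.
#' @export
run_gwas <- function(phenotypes, trait, genotypes, covariates = NULL,
                     pca_scores = NULL, alpha = 0.05) {
  if (!trait %in% names(phenotypes))
    stop(sprintf("trait '%s' is not a phenotype column", trait))
  ids <- intersect(genotypes$samples, phenotypes$animal_id)
  if (length(ids) == 0L) stop("no overlapping animal IDs between phenotypes and genotypes")
  gm <- genotypes[match(ids, genotypes$samples), ]
  ph <- phenotypes[match(ids, phenotypes$animal_id), , drop = FALSE]
  y <- as.numeric(ph[[trait]])
  covar <- NULL
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(ph))
    if (length(miss)) stop(sprintf("covariate column(s) not found: %s",
                                   paste(miss, collapse = ", ")))
    covar <- as.matrix(ph[, covariates, drop = FALSE])
  }
  if (!is.null(pca_scores)) {
    sc <- pca_scores[match(ids, rownames(pca_scores)), , drop = FALSE]
    if (anyNA(sc)) stop("pca_scores lack rows for some scanned samples")
    covar <- if (is.null(covar)) sc else cbind(covar, sc)
  }
  m <- ncol(gm$calls)
  beta <- se <- tv <- pv <- rep(NA_real_, m)
  nmiss <- integer(m)
  reason <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    r <- snp_regression(y, gm$calls[, j], covar)
    beta[j] <- r$beta; se[j] <- r$se; tv[j] <- r$t; pv[j] <- r$p
    nmiss[j] <- r$n_used; reason[j] <- r$reason
  }
  out <- data.frame(CHR = gm$map$chrom, SNP = gm$map$id, BP = gm$map$bp,
                    A1 = gm$map$a1, NMISS = nmiss, BETA = beta, SE = se,
                    STAT = tv, P = pv, REASON = reason,
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "threshold") <- bonferroni_threshold(alpha, m)
  class(out) <- c("gwas_scan", "data.frame")
  out
}

#' @export
print.gwas_scan <- function(x, n = 6L, ...) {
  th <- attr(x, "threshold")
  cat(sprintf("<gwas_scan: trait '%s', %d SNPs, Bonferroni p < %.3g>\n",
              attr(x, "trait"), nrow(x), th$threshold))
  hits <- sum(x$P < th$threshold, na.rm = TRUE)
  cat(sprintf("  significant SNPs: %d\n", hits))
  ord <- order(x$P)
  cat("  top associations:\n")
  print.data.frame(utils::head(x[ord, c("CHR", "SNP", "BP", "BETA", "SE", "STAT", "P")], n),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.gwas_scan <- function(object, ...) {
  th <- attr(object, "threshold")
  p <- object$P[is.finite(object$P)]
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  structure(list(trait = attr(object, "trait"),
                 n_snps = nrow(object),
                 n_tested = sum(is.finite(object$P)),
                 threshold = th,
                 n_significant = sum(p < th$threshold),
                 lambda_gc = lambda,
                 min_p = min(p),
                 top = object[order(object$P)[seq_len(min(5L, nrow(object)))], ]),
            class = "summary.gwas_scan")
}

#' @export
print.summary.gwas_scan <- function(x, ...) {
  cat(sprintf("GWAS scan of '%s': %d SNPs (%d tested)\n", x$trait, x$n_snps, x$n_tested))
  cat(sprintf("  Bonferroni: alpha %g / m %d -> p < %.4g; %d significant\n",
              x$threshold$alpha, x$threshold$m, x$threshold$threshold, x$n_significant))
  cat(sprintf("  genomic-control lambda (informational): %.3f; min p = %.3g\n",
              x$lambda_gc, x$min_p))
  print.data.frame(x$top[, c("CHR", "SNP", "BP", "BETA", "SE", "STAT", "P")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' QQ-plot data for a set of p-values
#'
#' Sorts observed p-values and pairs them with uniform-order-statistic
#' expectations: `expected_i = -log10((i - 0.5) / m)` for rank i of m.
#'
#' @param p vector of p-values in (0, 1\] (NAs dropped).
#' @return data.frame with columns `expected` and `observed` (both -log10
#'   scale, expected ascending).
#' @export
qq_data <- function(p) {
  bad <- which(!is.na(p) & (p <= 0 | p > 1))
  if (length(bad))
    stop(sprintf("p-value out of (0, 1] at position %d (%g)", bad[1], p[bad[1]]))
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no finite p-values")
  m <- length(p)
  obs <- -log10(sort(p, decreasing = TRUE))
  exp_ <- -log10(((m:1) - 0.5) / m)
  data.frame(expected = exp_, observed = obs)
}

#' Manhattan-plot data for an association table
#'
#' Lays chromosomes end to end: the cumulative genome coordinate of a SNP is
#' its bp position plus the summed lengths (max bp) of all preceding
#' chromosomes. Positions must already be sorted within each chromosome.
#'
#' @param assoc a `gwas_scan` or data.frame with `CHR`, `BP`, `P`.
#' @return data.frame with `CHR`, `BP`, `coord` (cumulative), `neglog10p`;
#'   the Bonferroni threshold of a `gwas_scan` input is attached as attribute
#'   `threshold_line` (-log10 scale).
#' @export
manhattan_data <- function(assoc) {
  need <- c("CHR", "BP", "P")
  if (!all(need %in% names(assoc))) stop("need columns CHR, BP, P")
  chrs <- unique(assoc$CHR)
  for (cc in chrs) {
    b <- assoc$BP[assoc$CHR == cc]
    if (is.unsorted(b, strictly = FALSE))
      stop(sprintf("positions on chromosome %s are unsorted; sort by (CHR, BP) first", cc))
  }
  len <- vapply(chrs, function(cc) max(assoc$BP[assoc$CHR == cc]), numeric(1))
  offset <- stats::setNames(cumsum(c(0, utils::head(len, -1L))), chrs)
  out <- data.frame(CHR = assoc$CHR, BP = assoc$BP,
                    coord = assoc$BP + offset[as.character(assoc$CHR)],
                    neglog10p = -log10(assoc$P))
  rownames(out) <- NULL
  th <- attr(assoc, "threshold")
  if (!is.null(th)) attr(out, "threshold_line") <- -log10(th$threshold)
  out
}

#' Plot a GWAS scan
#'
#' Base-graphics Manhattan and QQ plots with the Bonferroni threshold line.
#'
#' @param x a `gwas_scan`.
#' @param type `"manhattan"` or `"qq"`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return the plotted data, invisibly.
#' @export
plot.gwas_scan <- function(x, type = c("manhattan", "qq"), ...) {
  type <- match.arg(type)
  th <- attr(x, "threshold")
  if (type == "manhattan") {
    md <- manhattan_data(x[is.finite(x$P), ])
    cols <- ifelse(as.integer(factor(md$CHR, levels = unique(md$CHR))) %% 2 == 0,
                   "grey40", "steelblue4")
    graphics::plot(md$coord, md$neglog10p, col = cols, pch = 20, cex = 0.5,
                   xlab = "cumulative genome coordinate (bp)",
                   ylab = expression(-log[10](p)),
                   main = sprintf("Manhattan: %s", attr(x, "trait")), ...)
    graphics::abline(h = -log10(th$threshold), col = "red", lty = 2)
    invisible(md)
  } else {
    qd <- qq_data(x$P)
    graphics::plot(qd$expected, qd$observed, pch = 20, cex = 0.5,
                   xlab = expression(Expected ~ -log[10](p)),
                   ylab = expression(Observed ~ -log[10](p)),
                   main = sprintf("QQ: %s", attr(x, "trait")), ...)
    graphics::abline(0, 1, col = "red", lty = 2)
    invisible(qd)
  }
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson r over pairwise-complete values, with the two-sided
#' p-value from `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3 paired finite values).
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 paired finite values")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation is undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0, n = n))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE), n = n)
}

#' Pairwise trait correlations
#'
#' All unordered trait pairs of a phenotype table, as a tidy table.
#'
#' @param phenotypes data.frame with `animal_id` and trait columns.
#' @param traits columns to correlate; default all non-ID numeric columns.
#' @return data.frame with `trait1`, `trait2`, `r`, `p`, `n`.
#' @export
trait_correlations <- function(phenotypes, traits = NULL) {
  if (is.null(traits))
    traits <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))],
                      "animal_id")
  if (length(traits) < 2L) stop("need at least two traits")
  pairs <- utils::combn(traits, 2L)
  out <- data.frame(trait1 = pairs[1, ], trait2 = pairs[2, ],
                    r = NA_real_, p = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    pc <- pearson_correlation(phenotypes[[pairs[1, k]]], phenotypes[[pairs[2, k]]])
    out$r[k] <- pc$r; out$p[k] <- pc$p; out$n[k] <- pc$n
  }
  out
}

#' Trait summary statistics
#'
#' Per-trait mean, standard error of the mean, coefficient of variation
#' (percent, sample SD with divisor n - 1), minimum, and maximum -- the usual
#' herd-characterization table.
#'
#' @param phenotypes data.frame with `animal_id` and trait columns.
#' @param traits columns to summarize; default all non-ID numeric columns.
#' @return data.frame with `trait`, `mean`, `sem`, `cv_pct`, `min`, `max`.
#' @export
trait_summary <- function(phenotypes, traits = NULL) {
  if (is.null(traits))
    traits <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))],
                      "animal_id")
  out <- data.frame(trait = traits, mean = NA_real_, sem = NA_real_,
                    cv_pct = NA_real_, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(traits)) {
    v <- phenotypes[[traits[k]]]
    v <- v[is.finite(v)]
    if (length(v) < 2L)
      stop(sprintf("trait '%s' has fewer than 2 finite values", traits[k]))
    s <- stats::sd(v)
    out$mean[k] <- mean(v)
    out$sem[k] <- s / sqrt(length(v))
    out$cv_pct[k] <- 100 * s / mean(v)
    out$min[k] <- min(v)
    out$max[k] <- max(v)
  }
  out
}

#' Write an association table as PLINK-style TSV
#'
#' Columns exactly `CHR SNP BP A1 NMISS BETA SE STAT P`.
#'
#' @param assoc a `gwas_scan`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_assoc_tsv <- function(assoc, path) {
  cols <- c("CHR", "SNP", "BP", "A1", "NMISS", "BETA", "SE", "STAT", "P")
  utils::write.table(assoc[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
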