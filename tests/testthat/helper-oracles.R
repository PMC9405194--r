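# Independent oracles and small fixture builders used across the suite.

# Levene-Haldane heterozygote distribution by the ratio recurrence
# (independent of the package's closed-form log-pmf route): returns the
# normalized probability of every attainable heterozygote count.
hwe_dist_recurrence <- function(n_dip, n1) {
  n1 <- min(n1, 2L * n_dip - n1)
  n2 <- 2L * n_dip - n1
  hs <- seq.int(n1 %% 2L, n1, by = 2L)
  pr <- numeric(length(hs))
  mid <- which.min(abs(hs - n1 * n2 / (2 * n_dip)))
  pr[mid] <- 1
  if (mid < length(hs)) {
    for (k in mid:(length(hs) - 1L)) {
      h <- hs[k]
      hom1 <- (n1 - h) / 2; hom2 <- (n2 - h) / 2
      pr[k + 1L] <- pr[k] * 4 * hom1 * hom2 / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1L) {
    for (k in mid:2L) {
      h <- hs[k]
      hom1 <- (n1 - h) / 2; hom2 <- (n2 - h) / 2
      pr[k - 1L] <- pr[k] * h * (h - 1) / (4 * (hom1 + 1) * (hom2 + 1))
    }
  }
  list(h = hs, pr = pr / sum(pr))
}

# exact-test p-value from the recurrence distribution
hwe_p_oracle <- function(n_hom1, n_het, n_hom2) {
  n_dip <- n_hom1 + n_het + n_hom2
  n1 <- 2L * n_hom1 + n_het
  d <- hwe_dist_recurrence(n_dip, n1)
  p_obs <- d$pr[match(n_het, d$h)]
  min(1, sum(d$pr[d$pr <= p_obs * (1 + 1e-9)]))
}

# brute-force convex hull perimeter: an edge (i, j) is on the hull iff all
# other points lie on one side; O(n^3), for sections of <= ~60 points in
# general position.
brute_hull_perimeter <- function(y, z) {
  n <- length(y)
  per <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sign((y - y[i]) * (z[j] - z[i]) - (z - z[i]) * (y[j] - y[i]))
    s <- s[-c(i, j)]
    if (all(s >= 0) || all(s <= 0))
      per <- per + sqrt((y[i] - y[j])^2 + (z[i] - z[j])^2)
  }
  per
}

# dense noiseless single-view ("all") cloud for one parameter set
dense_cloud <- function(sp, seed = 1) {
  cl <- generate_animal_cloud(sp, poses = identity_pose(), seed = seed)
  fuse_views(cl$views, cl$transforms)
}

# small genotype matrix built by hand
toy_genotypes <- function(calls, chrom = NULL, bp = NULL) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  genotype_matrix(calls,
                  data.frame(chrom = chrom, id = sprintf("s%02d", seq_len(m)),
                             bp = bp, a1 = rep("A", m), a2 = rep("G", m),
                             stringsAsFactors = FALSE),
                  sprintf("an%02d", seq_len(nrow(calls))))
}

# numerical ellipse arc length (independent of the Ramanujan formula)
ellipse_perimeter_numeric <- function(a, b) {
  4 * stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}
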