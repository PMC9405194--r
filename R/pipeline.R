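# End-to-end orchestration: simulate genotypes and phenotypes, build one
# synthetic animal cloud per phenotype record, fuse and measure it, run QC
# and the per-trait association scans, and write every intermediate artifact
# plus a manifest with hashes. Reruns with the same config and seed are
# byte-identical for all text artifacts.

GEOMETRIC_TRAITS <- c("withers_height_cm", "hip_height_cm",
                      "chest_width_cm", "chest_girth_cm")

#' Pipeline run configuration
#'
#' Collects every tunable of the simulate / measure / qc / gwas chain with
#' validated defaults. All values can be overridden by a YAML config file
#' (see [read_run_config()]).
#'
#' @param seed root RNG seed; stage seeds are derived by fixed offsets.
#' @param n_samples,n_snps panel dimensions.
#' @param maf_low,maf_high,missing_rate genotype simulation settings.
#' @param n_causal,effect_sizes,n_hwe_violating,n_het_outliers,n_subpops,fst_like_divergence
#'   further [genotype_sim_params()] settings.
#' @param points_per_view,noise_sd cloud density and sensor noise for the
#'   per-animal synthetic clouds (the pipeline default is lighter than the
#'   generator's stand-alone default to keep a 96-head herd quick).
#' @param landmarks `"auto"` (heuristic detection) or `"true"`
#'   (generator-supplied).
#' @param write_clouds write per-view PLY files for each animal (off by
#'   default: a herd of clouds is large).
#' @param qc [qc_thresholds()] list.
#' @param pca_k PCA components in the QC report.
#' @param traits trait columns to scan.
#' @param covariates,pca_covariates association covariates: phenotype column
#'   names and/or a number of leading PC scores.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(seed = 17L, n_samples = 96L, n_snps = 5000L,
                       maf_low = 0.1, maf_high = 0.5, missing_rate = 0.01,
                       n_causal = 0L, effect_sizes = numeric(0),
                       n_hwe_violating = 0L, n_het_outliers = 0L,
                       n_subpops = 1L, fst_like_divergence = 0,
                       points_per_view = 4000L, noise_sd = 0.005,
                       landmarks = c("true", "auto"), write_clouds = FALSE,
                       qc = qc_thresholds(), pca_k = 10L,
                       traits = default_trait_panel()$trait,
                       covariates = NULL, pca_covariates = 0L,
                       alpha = 0.05) {
  landmarks <- match.arg(landmarks)
  geno <- genotype_sim_params(
    n_samples = n_samples, n_snps = n_snps, maf_low = maf_low,
    maf_high = maf_high, missing_rate = missing_rate, n_causal = n_causal,
    effect_sizes = effect_sizes, n_hwe_violating = n_hwe_violating,
    n_het_outliers = n_het_outliers, n_subpops = n_subpops,
    fst_like_divergence = fst_like_divergence, seed = seed + 1L)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(points_per_view >= 1, noise_sd >= 0)
  structure(list(seed = as.integer(seed), geno = geno,
                 points_per_view = as.integer(points_per_view),
                 noise_sd = noise_sd, landmarks = landmarks,
                 write_clouds = isTRUE(write_clouds),
                 qc = do.call(qc_thresholds, qc[names(qc) %in%
                   names(formals(qc_thresholds))]),
                 pca_k = as.integer(pca_k),
                 traits = traits, covariates = covariates,
                 pca_covariates = as.integer(pca_covariates),
                 alpha = alpha),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; unknown keys are an
#' error so silent typos cannot change a run. Values in `overrides` (e.g.
#' from command-line flags) take precedence.
#'
#' @param path YAML file path.
#' @param overrides named list applied on top of the file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(run_config, cfg)
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%OS1 "), "[morphogwas] ",
                       sprintf(fmt, ...))
}

#' Run the full pipeline
#'
#' Stages, in order: (1) simulate genotypes with planted violations;
#' (2) simulate phenotypes from the additive model; (3) generate one
#' three-view synthetic cloud per animal calibrated to its four geometric
#' traits, fuse it with the true transforms, and measure it; (4) run the QC
#' chain; (5) scan every configured trait; (6) write trait correlations and
#' the summary table. Every artifact is a plain-text TSV/PLY under `out_dir`
#' and the manifest records md5 hashes, counts, thresholds, and per-stage
#' timings. A stage failure writes a `FAILED` marker naming the stage and
#' rethrows.
#'
#' @param config a `run_config` (or the path of a YAML file).
#' @param out_dir output directory, created if missing.
#' @param verbose print timestamped per-stage progress.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory %s", out_dir))
  manifest <- list(package = "morphogwas",
                   version = as.character(utils::packageVersion("morphogwas")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed,
                   config = unclass_recursive(config),
                   stages = list())
  t_all <- proc.time()[3]
  current_stage <- "setup"
  on_fail <- function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", current_stage,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  }
  add_stage <- function(name, t0, files, info = list()) {
    manifest$stages[[name]] <<- c(list(
      elapsed_s = round(proc.time()[3] - t0, 3),
      files = as.list(tools::md5sum(file.path(out_dir, files)))), info)
  }
  tryCatch({
    # stage 1: genotypes -------------------------------------------------
    current_stage <- "simulate_genotypes"
    t0 <- proc.time()[3]
    stage_log(verbose, "simulating %d x %d genotypes",
              config$geno$n_samples, config$geno$n_snps)
    sim <- generate_genotype_matrix(config$geno)
    write_ped(sim$genotypes, file.path(out_dir, "genotypes.ped"),
              file.path(out_dir, "genotypes.map"))
    write_genotype_tsv(sim$genotypes, file.path(out_dir, "genotypes.tsv"))
    truth_df <- data.frame(
      category = c(rep("hwe_violating_snp", length(sim$truth$hwe_violating_snps)),
                   rep("low_call_snp", length(sim$truth$low_call_snps)),
                   rep("rare_snp", length(sim$truth$rare_snps)),
                   rep("het_outlier_sample", length(sim$truth$het_outlier_samples)),
                   rep("low_call_sample", length(sim$truth$low_call_samples))),
      index = c(sim$truth$hwe_violating_snps, sim$truth$low_call_snps,
                sim$truth$rare_snps, sim$truth$het_outlier_samples,
                sim$truth$low_call_samples))
    utils::write.table(truth_df, file.path(out_dir, "truth_record.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("simulate_genotypes", t0,
              c("genotypes.ped", "genotypes.map", "genotypes.tsv", "truth_record.tsv"),
              list(n_samples = config$geno$n_samples, n_snps = config$geno$n_snps))

    # stage 2: phenotypes ------------------------------------------------
    current_stage <- "simulate_phenotypes"
    t0 <- proc.time()[3]
    stage_log(verbose, "simulating phenotypes (%d traits)", nrow(default_trait_panel()))
    phen <- generate_phenotypes(sim$genotypes, config$geno,
                                exclude_snps = c(sim$truth$hwe_violating_snps,
                                                 sim$truth$low_call_snps,
                                                 sim$truth$rare_snps))
    write_phenotype_tsv(phen$phenotypes, file.path(out_dir, "phenotypes_true.tsv"))
    add_stage("simulate_phenotypes", t0, "phenotypes_true.tsv")

    # stage 3: clouds + measurement --------------------------------------
    current_stage <- "measure_clouds"
    t0 <- proc.time()[3]
    stage_log(verbose, "building and measuring %d animal clouds (%d pts/view)",
              config$geno$n_samples, config$points_per_view)
    measured <- measure_herd(phen$phenotypes, noise_sd = config$noise_sd,
                             points_per_view = config$points_per_view,
                             landmarks = config$landmarks,
                             seed = config$seed + 3L,
                             cloud_dir = if (config$write_clouds)
                               file.path(out_dir, "clouds") else NULL)
    write_phenotype_tsv(measured, file.path(out_dir, "phenotypes_measured.tsv"))
    add_stage("measure_clouds", t0, "phenotypes_measured.tsv",
              list(landmarks = config$landmarks))

    # stage 4: QC ---------------------------------------------------------
    current_stage <- "qc"
    t0 <- proc.time()[3]
    stage_log(verbose, "running QC")
    qc <- run_qc(sim$genotypes, config$qc, pca_k = config$pca_k)
    write_ped(qc$genotypes, file.path(out_dir, "genotypes_qc.ped"),
              file.path(out_dir, "genotypes_qc.map"))
    write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"),
                    file.path(out_dir, "pca_scores.tsv"))
    qcfiles <- c("genotypes_qc.ped", "genotypes_qc.map", "qc_report.tsv")
    if (file.exists(file.path(out_dir, "pca_scores.tsv")))
      qcfiles <- c(qcfiles, "pca_scores.tsv")
    add_stage("qc", t0, qcfiles,
              list(surviving = as.list(qc$report$surviving),
                   removed = lapply(qc$report$removed, length),
                   thresholds = qc$report$thresholds))

    # stage 5: GWAS -------------------------------------------------------
    current_stage <- "gwas"
    t0 <- proc.time()[3]
    m_post <- ncol(qc$genotypes$calls)
    th <- bonferroni_threshold(config$alpha, m_post)
    stage_log(verbose, "scanning %d traits over %d SNPs (threshold %.3g)",
              length(config$traits), m_post, th$threshold)
    pcs <- if (config$pca_covariates > 0L && !is.null(qc$report$pca))
      qc$report$pca$scores[, seq_len(config$pca_covariates), drop = FALSE]
    else NULL
    gfiles <- character(0)
    scan_info <- list()
    for (tr in config$traits) {
      scan <- run_gwas(measured, tr, qc$genotypes,
                       covariates = config$covariates, pca_scores = pcs,
                       alpha = config$alpha)
      stem <- paste0("assoc_", tr)
      write_assoc_tsv(scan, file.path(out_dir, paste0(stem, ".tsv")))
      md <- manhattan_data(scan[is.finite(scan$P), ])
      utils::write.table(md, file.path(out_dir, paste0("manhattan_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      qd <- qq_data(scan$P)
      utils::write.table(qd, file.path(out_dir, paste0("qq_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      gfiles <- c(gfiles, paste0(stem, ".tsv"), paste0("manhattan_", tr, ".tsv"),
                  paste0("qq_", tr, ".tsv"))
      scan_info[[tr]] <- list(n_significant = sum(scan$P < th$threshold, na.rm = TRUE),
                              min_p = min(scan$P, na.rm = TRUE))
    }
    add_stage("gwas", t0, gfiles,
              list(m_post_qc = m_post, alpha = config$alpha,
                   bonferroni_threshold = th$threshold, scans = scan_info))

    # stage 6: report -----------------------------------------------------
    current_stage <- "report"
    t0 <- proc.time()[3]
    stage_log(verbose, "writing correlations and trait summary")
    utils::write.table(trait_correlations(measured),
                       file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(trait_summary(measured),
                       file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("report", t0, c("correlations.tsv", "summary.tsv"))
  }, error = on_fail)
  manifest$elapsed_s <- round(proc.time()[3] - t_all, 3)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log(verbose, "done in %.1f s", manifest$elapsed_s)
  invisible(manifest)
}

# strip S3 classes so the config serializes cleanly to JSON
unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

#' Measure a synthetic herd
#'
#' For each phenotype record, calibrates an animal surface to the four
#' geometric traits, renders three noisy views, fuses them with the true
#' transforms, and measures the fused cloud. Live weight and meat output are
#' pass-through columns.
#'
#' @param phenotypes data.frame with `animal_id` and the four geometric trait
#'   columns (cm).
#' @param noise_sd,points_per_view cloud generation settings.
#' @param landmarks `"true"` (generator-supplied) or `"auto"` (heuristic
#'   detection).
#' @param seed RNG root for the herd; animal i uses `seed + i`.
#' @param cloud_dir if non-NULL, per-view PLY files and transform files are
#'   written there.
#' @return data.frame shaped like `phenotypes` with measured values in the
#'   geometric trait columns.
#' @export
measure_herd <- function(phenotypes, noise_sd = 0.005, points_per_view = 4000,
                         landmarks = c("true", "auto"), seed = 1L,
                         cloud_dir = NULL) {
  landmarks <- match.arg(landmarks)
  stopifnot(all(c("animal_id", GEOMETRIC_TRAITS) %in% names(phenotypes)))
  if (!is.null(cloud_dir)) dir.create(cloud_dir, recursive = TRUE, showWarnings = FALSE)
  out <- phenotypes
  for (i in seq_len(nrow(phenotypes))) {
    pr <- phenotypes[i, ]
    sp <- shape_params_for_measurements(
      withers_height_cm = pr$withers_height_cm,
      hip_height_cm = pr$hip_height_cm,
      chest_width_cm = pr$chest_width_cm,
      chest_girth_cm = pr$chest_girth_cm,
      noise_sd = noise_sd, points_per_view = points_per_view)
    cl <- generate_animal_cloud(sp, seed = seed + i)
    fused <- fuse_views(cl$views, cl$transforms)
    meas <- measure_animal(fused,
                           landmarks = if (landmarks == "true") cl$landmarks else "auto",
                           plane = "fixed_z0")
    out$withers_height_cm[i] <- meas$withers_height_cm
    out$hip_height_cm[i] <- meas$hip_height_cm
    out$chest_width_cm[i] <- meas$chest_width_cm
    out$chest_girth_cm[i] <- meas$chest_girth_cm
    if (!is.null(cloud_dir)) {
      for (v in names(cl$views)) {
        write_cloud(cl$views[[v]],
                    file.path(cloud_dir, sprintf("%s_%s.ply", pr$animal_id, v)))
        write_transform(cl$transforms[[v]],
                        file.path(cloud_dir, sprintf("%s_%s_transform.txt", pr$animal_id, v)))
      }
    }
  }
  out
}
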