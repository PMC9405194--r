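# Text-format I/O for genotypes and phenotypes: PLINK PED/MAP, a simple
# 0/1/2/NA genotype TSV, and the phenotype TSV.

#' Write and read PLINK PED/MAP text files
#'
#' PED rows are `FID IID PAT MAT SEX PHENO` followed by one allele pair per
#' SNP (`0 0` for a missing call); the MAP has columns chromosome, SNP id,
#' genetic distance (cM, written as 0), and bp position. Genotypes are coded
#' as counts of the A1 allele. Only autosomal chromosome labels (1-29) are
#' kept when reading; other SNPs (X/Y/mitochondrial or unmapped) are dropped,
#' mirroring the usual pre-analysis step.
#'
#' @param genotypes a [genotype_matrix()].
#' @param ped,map file paths.
#' @return `write_ped` returns the paths invisibly; `read_ped` returns a
#'   [genotype_matrix()].
#' @export
write_ped <- function(genotypes, ped, map) {
  gm <- genotypes
  calls <- gm$calls
  n <- nrow(calls); m <- ncol(calls)
  a1 <- gm$map$a1; a2 <- gm$map$a2
  rows <- character(n)
  for (i in seq_len(n)) {
    g <- calls[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a1, a2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a1, a2))
    rows[i] <- paste(c(gm$samples[i], gm$samples[i], "0", "0", "0", "-9",
                       rbind(al1, al2)), collapse = " ")
  }
  writeLines(rows, ped)
  writeLines(sprintf("%d %s 0 %d", gm$map$chrom, gm$map$id, gm$map$bp), map)
  invisible(c(ped = ped, map = map))
}

#' @rdname write_ped
#' @export
read_ped <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "id", "cm", "bp"))
  lines <- readLines(ped, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("%s: empty PED file", ped))
  m <- nrow(mp)
  n <- length(lines)
  samples <- character(n)
  allele1 <- matrix(NA_character_, n, m)
  allele2 <- matrix(NA_character_, n, m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * m)
      stop(sprintf("%s: line %d: expected %d fields for %d SNPs, got %d",
                   ped, i, 6L + 2L * m, m, length(tok)))
    samples[i] <- tok[2]
    al <- matrix(tok[-(1:6)], nrow = 2L)
    al[al == "0"] <- NA_character_
    allele1[i, ] <- al[1, ]
    allele2[i, ] <- al[2, ]
  }
  # A1 = minor allele per SNP (ties broken by allele order of appearance)
  calls <- matrix(NA_integer_, n, m)
  a1 <- rep("0", m); a2 <- rep("0", m)
  for (j in seq_len(m)) {
    obs <- c(allele1[, j], allele2[, j])
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) next
    lev <- unique(obs)
    if (length(lev) > 2L)
      stop(sprintf("%s: SNP %s has more than two alleles (%s)",
                   ped, mp$id[j], paste(lev, collapse = "/")))
    cnt <- tabulate(match(obs, lev), nbins = length(lev))
    ord <- order(cnt)          # minor first; stable for ties
    lev <- lev[ord]
    a1[j] <- lev[1]
    a2[j] <- if (length(lev) > 1L) lev[2] else "0"
    calls[, j] <- (allele1[, j] == a1[j]) + (allele2[, j] == a1[j])
  }
  keep <- mp$chrom %in% seq_len(BOS_TAURUS_AUTOSOMES)
  gm <- genotype_matrix(calls, data.frame(chrom = mp$chrom, id = mp$id,
                                          bp = mp$bp, a1 = a1, a2 = a2,
                                          stringsAsFactors = FALSE), samples)
  gm[, keep]
}

#' Write and read the genotype TSV dialect
#'
#' A header line `snp_id chrom bp a1 a2 <sample ids...>` is followed by one
#' row per SNP with calls 0/1/2 or `NA`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path.
#' @return `write_genotype_tsv` returns `path` invisibly; `read_genotype_tsv`
#'   returns a [genotype_matrix()].
#' @export
write_genotype_tsv <- function(genotypes, path) {
  gm <- genotypes
  df <- data.frame(snp_id = gm$map$id, chrom = gm$map$chrom, bp = gm$map$bp,
                   a1 = gm$map$a1, a2 = gm$map$a2,
                   t(gm$calls), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("snp_id", "chrom", "bp", "a1", "a2")
  if (!all(meta %in% names(df)[1:5]))
    stop(sprintf("%s: expected leading columns %s", path, paste(meta, collapse = ", ")))
  samples <- setdiff(names(df), meta)
  calls <- t(as.matrix(df[, samples, drop = FALSE]))
  genotype_matrix(calls,
                  data.frame(chrom = df$chrom, id = df$snp_id, bp = df$bp,
                             a1 = df$a1, a2 = df$a2, stringsAsFactors = FALSE),
                  samples)
}

#' Write and read the phenotype TSV
#'
#' Tab-separated with header `animal_id` followed by one column per trait.
#'
#' @param phenotypes data.frame keyed by `animal_id`.
#' @param path file path.
#' @return `write_phenotype_tsv` returns `path` invisibly;
#'   `read_phenotype_tsv` returns the data.frame.
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  if (!"animal_id" %in% names(phenotypes))
    stop("phenotype table must have an animal_id column")
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"animal_id" %in% names(df))
    stop(sprintf("%s: no animal_id column", path))
  df$animal_id <- as.character(df$animal_id)
  df
}
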