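Package: morphogwas
Title: Body Measurements from Multi-View Point Clouds and Genome-Wide
    Association Scans for Beef Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-contact morphometry of beef cattle from fused
    multi-view depth-camera point clouds (withers height, hip height, chest
    width, and chest girth via plane-slice convex-hull perimeters) and for
    genome-wide association scans of those traits. Includes a synthetic-data
    generator for animal-shaped point clouds with analytic ground-truth
    measurements and for genotype/phenotype panels with planted quality-control
    violations and quantitative trait loci; a SNP and sample quality-control
    chain (call rate, minor allele frequency, exact Hardy-Weinberg test,
    heterozygosity outliers, principal-component stratification check);
    per-SNP additive linear-model association tests with Bonferroni
    thresholds; and Manhattan/QQ plot data, trait correlations, and summary
    tables. An end-to-end pipeline reproduces the whole simulate, measure,
    QC, scan workflow deterministically from one seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
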