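Package: popcurate
Title: Neutral SNP Curation and Hierarchical Population Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curates neutral SNP panels from target-capture variant calls and
    analyses hierarchical population structure. Provides an ordered filtering
    cascade (per-genotype depth masking, minor-allele-frequency and
    missingness filters, contig SNP-density control, linkage-disequilibrium
    pruning, inter-SNP spacing, Bayesian FST-outlier removal, and a
    permutation screen for excess-heterozygosity paralog artefacts), Weir and
    Cockerham F-statistics, nested analysis of molecular variance,
    heterozygosity summaries, discriminant analysis of principal components,
    an admixture-model Gibbs sampler with Evanno delta-K model choice,
    redundancy analysis of population allele frequencies against orthogonal
    spatial polynomials, and a Balding-Nichols hierarchical genotype
    simulator with known ground truth for end-to-end validation.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
VignetteBuilder: knitr
Config/testthat/edition: 3
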