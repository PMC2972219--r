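Package: hapscan
Title: Haplotype-Pair Association Scans for Multiallelic Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative-trait association mapping with panels of
    multiallelic (microsatellite) markers under selective genotyping of
    phenotypic extremes. Implements expectation-maximization estimation of
    two-locus haplotype frequencies from unphased genotypes, Fisher's exact
    test on r x 2 haplotype count tables with minor-haplotype filtering and
    Bonferroni chromosome- and genome-wise thresholds, exact and Monte Carlo
    Hardy-Weinberg tests for multiple alleles, the standardized multiallelic
    linkage-disequilibrium coefficient (chi-square prime), effective
    population size estimation from LD decay via Sved's drift-recombination
    curve, degrees-of-freedom-weighted genomic-control lambda, and
    candidate-locus genotype-phenotype summaries. A Wright-Fisher forward
    simulator with recombination on a genetic map generates synthetic study
    populations with drift-generated LD for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
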