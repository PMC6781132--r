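Package: ploidyclust
Title: Clustering Power and Ploidy Bias in Simulated Mixed-Ploidy Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-time simulation of allele frequencies in two mixed-ploidy
    (diploid + autotetraploid) populations connected by migration, genotype
    sampling under three marker encodings (known dosage, unknown dosage,
    dominant presence/absence), two in-package clustering engines (k-means on
    within-individual allele frequencies and a ploidy-aware Bayesian admixture
    Gibbs sampler), and the beta-statistic that separates correct clustering
    by population from spurious clustering by ploidy level. Includes scenario
    presets for migration-rate sweeps, loci-versus-individuals trade-offs and
    genotyping-by-sequencing designs, plus writers for Structure-style and
    PLINK-style input files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
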