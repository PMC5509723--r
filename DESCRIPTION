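Package: landgen
Title: Phylogeographic Inference and Landscape Genomics for Sequence and
    Dominant-Marker Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for joint phylogeographic and landscape-genomic
    analysis of intraspecific data: haplotype and nucleotide diversity from
    aligned sequences, neutrality tests (Tajima's D, Fu's Fs, R2) with
    coalescent-simulation p-values, mismatch-distribution fitting under the
    sudden-expansion model with expansion-time dating, dominant-marker (AFLP)
    allele-frequency estimation and diversity, pairwise FST, AMOVA, DAPC-style
    clustering, FST-outlier scans (an FDIST-style neutral envelope and a
    simplified Bayesian posterior-odds model), univariate logistic
    environmental association with Nagelkerke pseudo-R2, and RDA-based
    variation partitioning. Includes coalescent and island-model simulators
    so every stage is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
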