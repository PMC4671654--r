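Package: nphp1sv
Title: Structural-Variant Haplotyping at the LCR-Laden Human NPHP1 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the complex low-copy-repeat (LCR) architecture of the
    human NPHP1 region on chromosome 2q13 and delineates the seven known
    structural-variant (SV) haplotypes (H1-H7) from multiple evidence types.
    Provides a coordinate-level locus model with inversion and
    deletion/insertion transforms and NAHR-susceptibility classification;
    synthetic-data generators for haplotype sequences, fosmid end-sequence-pair
    libraries, single-molecule restriction maps (Rmaps), array-CGH probe log2
    ratios, and windowed read-depth copy number; detectors for paralogous LCR
    blocks, pairwise identities, and PRDM9 recombination-hotspot motifs; a
    dynamic-programming Rmap aligner with an explicit sizing/cut error model
    and haplotype calling by model selection; copy-number estimation rules for
    intra- and inter-species aCGH; population copy-number statistics
    (Kruskal-Wallis, Welch t); and an evidence integrator producing diploid
    (or mosaic) genotype reports with NAHR-protection classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
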