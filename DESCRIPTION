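Package: radmut
Title: Mutation Spectra, Deletion Microhomology and Survival Curves for
    Radiation Mutagenesis Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for genome-wide characterization of mutations induced by
    ionizing radiation in resequenced mutant cohorts, with an emphasis on
    plants deficient in non-homologous end joining (NHEJ). Implements
    allele-frequency and cross-sample filtering of candidate variant calls
    with zygosity assignment, left-alignment normalization of indels,
    merging of nearby variants into mutation events with a seven-way
    classification (single-base substitutions, single-base and longer
    insertions/deletions, complex-type events and structural variants),
    apparent-microhomology scoring at deletion junctions, per-base-pair and
    per-Gray mutation-rate summaries with strand-collapsed substitution
    spectra, and least-squares fitting of the single-hit multitarget
    survival model with quasi-threshold dose (Dq) derivation. A synthetic
    data generator produces reference genomes, ground-truth mutation sets,
    candidate calls with read-support allele frequencies, M2 segregation of
    induced heterozygous mutations, and dose-survival tables, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
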