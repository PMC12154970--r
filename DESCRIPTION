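Package: mthet
Title: Age-Related Mitochondrial DNA Heteroplasmy Analysis in Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the accumulation of heteroplasmic
    mitochondrial DNA (mtDNA) single-nucleotide variants with age in
    large blood-based sequencing cohorts. Implements sample- and
    variant-level quality control with a per-individual Poisson
    read-depth detection threshold, mtDNA copy-number derivation and
    covariate residualisation, strand- and region-aware mutational
    spectrum statistics with trinucleotide contexts and single-base
    substitution signature correlation, nonparametric dN/dS estimation
    with a per-individual sampling null, and clonal-hematopoiesis
    comparisons via age- and sex-matched resampling, sibling variant
    sharing, locus clumping, inverse-variance-weighted effect-size
    regression and disease association. A synthetic cohort generator
    emulating cryptic replication-error mutation accrual amplified by
    clonal expansion makes every stage testable without access to
    restricted biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
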