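Package: scissile
Title: Protease Cleavage-Site Mapping, Subsite Specificity and Hemocidin
    Annotation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing endopeptidase specificity from
    degradomic and fluorogenic-substrate data. Computes monoisotopic and
    average peptide masses for internally quenched (Abz/EDDnp) substrates,
    enumerates candidate cleavage fragments and infers scissile bonds from
    LC/MS ion lists, maps hemoglobin-derived product peptides onto parent
    chains to build Schechter-Berger subsite frequency statistics and
    annotate hemocidins (antimicrobial hemoglobin fragments), normalizes
    positional-scanning synthetic combinatorial library (PS-SCL) profiles
    into specificity matrices, predicts cleavage in silico, and fits
    apparent first-order enzyme inactivation kinetics. Seeded synthetic-data
    generators emulate every input so the full pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
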