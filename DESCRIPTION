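Package: mbaq
Title: Median-Based Absolute Protein Quantification with a Generic
    Internal Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Label-free absolute quantification of proteins from
    peptide-level XIC peak areas using a codigested chimeric internal
    standard. The median peak area of the standard's equimolar tryptic
    peptides serves as a single-point molar calibrant; proteins are
    quantified from low-variance (BestN) peptide subsets selected by
    coefficient of variation. Includes calibration quality statistics
    (normalized median abundance, near-median fraction), bootstrap
    analysis of median stability versus peptide number, design tools for
    scrambled standard peptides (tryptic digestion, proteotypic
    filtering, constrained residue swaps and substitutions with
    monoisotopic-mass and hydropathy checks, uniqueness screening
    against proteome databases), and a synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
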