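Package: codonexpr
Title: Codon-Level Indices and Predictors of Protein Expression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the influence of individual codons (and adjacent codon
    pairs) on protein expression from matched coding sequences and quantitative
    proteome data. Implements the Codon Expression Index (per-codon Z-scores of
    the Kendall tau-a rank correlation between codon frequency and protein
    abundance), Codon Productivity (abundance-weighted mean expression per
    codon), and the derived cross-validated expression predictors CEIS, CPS and
    CPEIS, together with a Codon Adaptation Index comparator trained with a
    top-quartile reference set, expression-class codon distributions, and a
    synthetic-data generator with planted per-codon effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
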