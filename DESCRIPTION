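Package: mutrobust
Title: Protein Mutational Robustness at the Genetic-Code and Codon Level
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Structurome-scale analysis of protein mutational robustness.
    Enumerates and classifies single- and multiple-base substitutions of
    codons under the standard genetic code, joins residue-level annotations
    (wild-type codon, relative solvent accessibility) with per-mutation
    folding free-energy changes (ddG), and computes stratified robustness
    statistics: stabilizing/neutral/destabilizing fractions, per-codon-position
    means with synonymous and degeneracy weighting, translation-error
    weighting, transition/transversion and BLOSUM62 stratification,
    used-versus-synonymous codon comparisons, codon-usage-bias
    classification, and RSA/length profiles. Ships a seedable synthetic
    structurome generator that emulates the statistical structure of
    curated X-ray structuromes so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
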