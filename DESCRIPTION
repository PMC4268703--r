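Package: kinlr
Title: Likelihood-Ratio Identification of Remains from Kinship and
    Uniparental Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Bayesian framework for identifying skeletal remains in
    cold missing-person cases by combining genetic and non-genetic lines
    of evidence.  Provides pedigree queries for uniparental lineages
    (matriline and patriline paths, meiosis counts, cousin terminology,
    matrilineal kinship networks), mitochondrial control-region haplotype
    comparison and conservative pseudocount match-probability estimation
    in rCRS coordinates, Y-STR haplotype comparison with a false-paternity
    exposure model, multiplicative likelihood-ratio combination of
    independent evidence items with prior-to-posterior conversion, and a
    seeded forward simulator of pedigrees, marker transmission and
    population haplotype databases for end-to-end validation with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
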