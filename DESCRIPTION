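Package: hmcscore
Title: Homologous Missense Constraint from Protein Domain Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue genetic constraint of missense variants by
    aggregating observed versus expected rare variation across evolutionarily
    equivalent positions ("meta-positions") of protein domain families. Every
    possible coding single-nucleotide variant is enumerated from transcript
    models, expected counts come from a trinucleotide mutability model with
    CpG-methylation and sequencing-coverage adjustment calibrated on
    synonymous variation, and the constraint score is the upper bound of the
    90% credible interval of the observed/expected rate ratio under a
    Poisson-Gamma model. Includes evaluation statistics (risk ratios across
    score bins, de novo mutation burden with exact Poisson intervals,
    case-control odds ratios, precision-sensitivity curves), a synthetic-data
    generator with known ground truth, and a file-based pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
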