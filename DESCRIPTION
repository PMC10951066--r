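Package: repdominance
Title: CD4 T Cell Repertoire Statistics and Epitope Immunodominance for
    Factor VIII
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of antigen-specific CD4 T cell
    repertoires built around coagulation factor VIII (FVIII) as the model
    self-antigen. Implements limiting-dilution precursor-frequency
    estimation from ELISPOT plates under the Poisson model, background
    subtraction of culture-shared clonotypes, Gini-Simpson clonality and
    top-fraction dominance statistics, CDR3beta length and composition
    profiles with a deterministic anchor alignment, V-J gene usage and
    pairing, cross-donor public clonotype detection, promiscuous MHC
    class II peptide selection from percentile-rank matrices, and
    immunodominance ranking of epitopes from donor-by-peptide response
    matrices. A seeded synthetic-data module generates every input the
    pipeline consumes, with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
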