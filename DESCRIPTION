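Package: neoscreen
Title: Neoantigen Candidate Screening for Multifocal Lung Adenocarcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline from per-focus somatic variant calls to
    ranked, filter-passing, multi-algorithm-harmonized mutant/wild-type
    peptide pairs. Parses MAF and annotated-VCF somatic calls, tallies
    variant classes and six-class SNV spectra, computes tumor mutational
    burden (TMB) and tumor neoantigen burden (TNB), enumerates 8-11-mer
    mutant peptides (including frameshift re-translation), applies the
    IC50-based high-binder filter, harmonizes binding scores across
    prediction algorithms onto a common 1-20 scale, selects top candidates,
    and screens for peptides shared across tumor foci of multifocal
    patients. Ships a synthetic-cohort simulator with known ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
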