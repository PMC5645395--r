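Package: mirmeta
Title: Conditional miRNA and TF Regulator Identification with Meta-Lasso
    and Pathway-Module Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies condition-specific (cancer type by stage) miRNA and
    transcription-factor regulators of genes by combining interaction-evidence
    scoring from chimeric-read (CLASH-style) binding-site data and TF
    binding-site annotations with a background-adjusted meta-Lasso regression
    fitted over hierarchically resampled sample subsets, then discovers
    k-miRNA regulatory modules that co-regulate pathways recurrently across
    conditions.  Includes binomial site-confidence filtering of chimeric
    reads, regulatory-score calculation for miRNA-mRNA and TF-gene pairs,
    Frisch-Waugh-Lovell adjustment for copy-number and methylation background,
    hypergeometric pathway enrichment with binomial involvement and recurrence
    tests under Benjamini-Hochberg FDR control, a Jaccard-based selection
    stability assessment, and a synthetic-data generator with planted
    regulators and modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    yaml,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
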