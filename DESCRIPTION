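Package: neoclone
Title: Clonal Evolution of Paired Pre- and Post-Chemotherapy Tumour Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis pipeline for paired pre- and post-treatment tumour
    sequencing of oesophageal adenocarcinoma cohorts: empirical somatic
    variant filtering with paired-sample relaxation, tumour purity
    estimation and post-treatment sample exclusion, copy-number-corrected
    cancer cell fraction clustering by binomial-mixture EM, per-patient
    classification of clonal dynamics (stable, genetic bottleneck,
    polyclonal), trinucleotide mutation-spectrum and NMF signature-shift
    analysis, arm-scale somatic copy number alteration calling from logR
    with pre/post sharing fractions, and the cohort-level association
    statistics. Includes a synthetic clonal-evolution cohort generator
    with known truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
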