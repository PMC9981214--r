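Package: xenopurity
Title: Tumor Purity Estimation for Xenograft and Syngeneic Mouse Tumor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tumor purity in preclinical mouse tumor models from
    sequencing-derived summaries. Implements a maximum-likelihood estimator of
    syngeneic tumor purity from variant read depths at cell-line-specific SNP
    sites under a binomial cancer:stroma mixture, the median-of-segments
    aggregation of a deep amplicon sequencing assay for patient-derived
    xenograft (PDX) purity, species assignment of reads from comparative
    alignment scores, germline/somatic variant classification from population
    allele frequencies, cross-species conservation and cohort prevalence,
    single-sample stromal/immune enrichment scoring (human, mouse-ortholog and
    hybrid versions) with loess score-to-purity calibration, and the
    cohort-level statistics used to characterise purity across models,
    passages, host strains and cancers. A synthetic-data module generates all
    inputs with known ground truth for validation.
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
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
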