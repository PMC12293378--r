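Package: ccmsurv
Title: Blood Chromatin Conformation Markers, Immune Signatures, and
    Treatment-Interaction Survival Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating binary blood chromatin conformation marker
    (CCM) calls to tumor immune gene-expression signatures and overall
    survival in a two-arm trial setting. Provides a synthetic cohort
    generator with a known proportional-hazards ground truth (treatment,
    tumor mutation burden, and marker-by-treatment-by-TMB interactions),
    immune signature scoring with median hi/lo splits, Wilcoxon and Fisher
    marker screens with FDR control, a three-step marker prioritization
    (subgroup count filter, nested-Cox dilution cascade, elastic-net Cox
    with cross-validation-frequency hyperparameter selection), Kaplan-Meier
    and Cox subgroup summaries, per-gene three-way interaction scans, and
    closest-gene interval annotation of marker loci.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
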