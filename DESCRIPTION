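Package: deptx
Title: Transcription-Factor Composite Z-Score Biomarkers for
    Inflammation-Related Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A whole-blood transcriptomics pipeline for studying
    inflammation-related depression in a paired pre/post bariatric-surgery
    design: sparse partial least squares (sPLS) gene selection against a
    continuous depression score, paired and unpaired differential expression
    with Benjamini-Hochberg FDR control, open upstream-regulator scoring
    (hypergeometric overlap and signed activation z-scores) against
    user-supplied transcription-factor target sets, transcript origin
    analysis with a bootstrap null, per-patient composite z-score biomarkers
    built from TF target genes, and the two-way ANOVA / regression layer
    that validates the biomarkers against MADRS depression scores. Ships a
    synthetic paired-cohort generator with latent TF-activation structure so
    the full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    limma,
    car,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    withr
Config/testthat/edition: 3
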