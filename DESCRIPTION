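Package: rootzone
Title: Tissue-Resolved RNA-Seq Gene Activity and Water-Deficit Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A statistical workflow for tissue-resolved bulk RNA-Seq experiments
    run under a control versus water-deficit contrast in an incomplete-block
    (sequencing-lane) design. Provides a synthetic-data generator with known
    ground truth for a 4-tissue x 2-treatment x replicated design; TMM plus
    covariate-smoother normalization offsets; a hierarchical empirical-Bayes
    negative-binomial model that calls genes active or inactive per tissue and
    condition from calibrated posterior exceedance probabilities; a taxonomy of
    activity dynamics (constitutive, stable, dynamic) with spatial change
    counting; precision-weighted differential expression with a random lane
    effect, moderated variances and FDR control; Fisher and chi-square category
    enrichment; and an orchestrated pipeline with sample-relationship
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
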