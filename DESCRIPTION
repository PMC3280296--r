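Package: arrayprep
Title: Spot-Level Microarray Quantification and Amplification-Bias Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies single-channel spotted microarrays from per-spot
    foreground intensities: blank-spot trimmed-mean background estimation,
    detection calls against a one-sided 95% upper confidence limit of the
    background, background subtraction, and global median normalization.
    Includes a replicate quality-control suite (pairwise Pearson correlation
    on log10 intensities, two-fold concordance, per-gene coefficient of
    variation with replicate-detection filters), consensus-detection Venn
    partitions across sample-preparation methods, and accuracy evaluation
    against qRT-PCR delta-Ct tables via Spearman rank correlation. A
    synthetic-study generator emulates in-vitro-transcription amplification
    bias (sequence-feature-dependent efficiency with linear-then-saturating
    kinetics) so the complete pipeline, from spot tables to accuracy
    reports, runs end to end on simulated hybridizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
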