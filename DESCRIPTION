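Package: chromexpr
Title: Predicting Gene Expression from Transcription-Factor Binding and
    Histone-Modification Signal Around the TSS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the effects of transcription-factor (TF) binding,
    histone modifications (HMs) and DNase-I hypersensitivity on gene
    expression levels. Aligned-tag tracks are binned into fixed-width
    windows flanking each transcription start site and depth-normalized;
    per-gene association strengths are computed as Gaussian-kernel-weighted
    sums (TFs) or plain bin sums (HMs/DNase); log-linear regression and
    epsilon-SVR models predict log2 RPKM under 10-fold cross-validation.
    Downstream analyses quantify statistical redundancy among factors:
    exhaustive feature-subset ("combination mode") evaluation, shrinkage
    partial-correlation network inference with leave-genes-out robustness,
    and gene-set-level comparison of TF-only versus HM-only predictive
    power. A synthetic-data generator with recorded ground truth supports
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
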