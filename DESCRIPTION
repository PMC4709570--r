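Package: sexconn
Title: Sex-Stratified Differential Expression and Differential Connectivity Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying sex-linked transcriptomic alterations in
    tumors and predicting perturbagens (drugs and genetic reagents) with
    sex-differential efficacy. Implements Wilcoxon rank-sum differential
    expression by sex and by tissue (tumor versus normal) stratified by sex,
    Benjamini-Hochberg adjustment, median fold changes, sex-chromosome
    enrichment, Fisher's-method pan-cancer meta-analysis, LASSO sex
    classification with cross-validated AUC, hypergeometric pathway
    over-representation with per-sex discordance summaries, construction of
    sensitivity and resistance expression signatures, a Connectivity-Map-style
    weighted Kolmogorov-Smirnov scorer over perturbagen rank profiles with
    signed-percentile normalization, and a sex-label permutation test that
    calibrates empirical p-values for male-female connectivity differences and
    classifies perturbagens as male-sensitive (Type I), female-sensitive
    (Type II), or sensitive in both sexes (Type III). Includes seeded
    synthetic cohort and perturbagen-library generators so the whole pipeline
    can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    fgsea,
    glmnet,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
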