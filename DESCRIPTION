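Package: brainrisk
Title: Combined Lifestyle Risk Scores and Their Association with Brain
    Structure and Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the joint contribution of lifestyle behaviours
    (alcohol consumption, smoking, physical activity, social integration) to the
    aging brain. Builds a combined lifestyle risk score from z-transformed
    behaviour measures with a stepwise-exclusion model family, performs
    vertex-wise surface GLMs with Monte-Carlo and permutation cluster-wise
    correction on triangulated cortical meshes, screens subcortical volumes with
    partial Spearman correlations, runs a seed-based resting-state functional
    connectivity pipeline (nuisance regression, band-pass filtering,
    eigenvariate seeds, Fisher-z maps, permutation cluster inference), and
    constructs a weighted allelic polygenic risk score for covariate adjustment.
    Includes a synthetic-cohort generator emulating the statistical structure of
    a population-based aging study, so the full pipeline is testable without
    access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
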