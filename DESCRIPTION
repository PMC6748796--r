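Package: crowdmask
Title: Concordance Analysis of Crowdsourced Histology Region Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts multi-participant polygonal tissue annotations into
    class label masks (with a default tissue class and expert correction
    overlays), quantifies inter-participant discordance with a pooled
    multi-class Dice statistic, analyses discordance by tissue class and
    annotator experience tier (rank tests, biclustered heatmap ordering,
    multidimensional scaling), evaluates pixel-level segmentation
    predictions (per-class ROC AUC, Dice, accuracy, confusion), and
    simulates multi-annotator cohorts with controllable boundary-jitter,
    class-confusion and region-miss error structure so that every stage of
    the analysis can be exercised without access to a slide archive.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    igraph,
    glmnet,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
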