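Package: paridis
Title: Ensemble Species Distribution Modelling, Niche Overlap, and
    Plastid Mini-Barcode Design for Medicinal Paris Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable reimplementation of a two-part
    analysis workflow for the medicinal herbs Paris polyphylla var.
    chinensis and var. yunnanensis: (1) presence-only ensemble species
    distribution modelling with pseudo-absence sampling, TSS/ROC committee
    selection, permutation variable importance, human-footprint impact
    quantification via Schoener's D, niche equivalency permutation tests
    in PCA-environment space, binary range-change and centroid-shift
    analysis, and long-term all-scenario cultivation-area delineation;
    and (2) discovery of species-diagnostic SNP/indel sites in aligned
    plastid genomes with 200-bp mini-barcode candidate design and seedling
    classification. A synthetic-data module (virtual landscapes, virtual
    species, future-scenario perturbations, two-group alignments with
    planted diagnostics) gives every stage a ground-truth recovery target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    MASS,
    mgcv,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
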