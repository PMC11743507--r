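Package: microshift
Title: Centroid-Offset Analysis of Diet-Induced Gut Microbiota Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies shifts in gut microbial community composition
    between experimental groups of a diet-intervention study.  Implements
    the GM offset statistic -- the Euclidean distance between group
    centroids on the first two axes of a principal-coordinates ordination
    of Bray-Curtis dissimilarities -- together with permutation inference,
    bootstrap intervals and ANOSIM; alpha diversity (Shannon,
    Gini-Simpson) and the Firmicutes/Bacteroidota ratio; group-level body
    weight and fasting blood glucose deltas with glucose-tolerance curve
    areas; per-genus differential abundance, core/specific genus
    partitions and genus-phenotype correlation networks; and a
    Dirichlet-multinomial simulator of the 4-group x 5-mouse x 2-timepoint
    intervention design with known ground truth, so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
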