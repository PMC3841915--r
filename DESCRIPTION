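Package: otunet
Title: Ecologically Optimal OTU Clustering Thresholds via Bipartite Network AIC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects an ecologically meaningful similarity threshold for
    clustering amplicon sequence types into operational taxonomic units
    (OTUs). Sequence types are clustered hierarchically across a grid of
    similarity levels and every clustering is scored by the AIC of a
    bipartite OTU-by-plot network model combining a binary occurrence
    likelihood with an abundance-weighted Poisson (or Binomial) likelihood;
    the AIC-minimising threshold is selected. Includes downstream
    network-ecology summaries (generalist/specialist/endemic classification,
    singletons, per-plot community tables, co-occurrence clustering) and a
    synthetic amplicon community generator with planted OTU structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    igraph,
    ape,
    mclust,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
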