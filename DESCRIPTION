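Package: keyreg
Title: Upstream Regulator Inference from Signed Causality Graphs of
    Regulated Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proposes upstream regulatory candidates (transcription factors,
    enzymes, protein complexes) for lists of regulated molecules. Biochemical
    reactions and regulatory effects are unified into "regulated reactions",
    compiled into a signed causality graph over quantity, availability and
    reaction-speed nodes, and signed influence is propagated by a
    parity-aware reachability closure. Candidates are ranked by coverage
    (number of targets explained with a consistent sign) and specificity
    (coverage weighted by a hypergeometric enrichment probability), with
    explicit handling of tied scores. Includes a synthetic scale-free
    knowledge-base generator with planted regulons, a benchmark harness
    measuring success-at-top-n against planted regulators, and topology
    statistics (power-law degree exponent, characteristic path length,
    diameter) for the extracted networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
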