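Package: groupness
Title: Association Networks and Permutation Inference for Mixed-Species Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying 'groupness' in mixed-species animal groups
    from focal instantaneous point samples of proximity. Builds
    group-by-individual matrices under the gambit of the group, computes
    simple-ratio-index (SRI) association matrices and SRI-weighted social
    networks, derives node- and species-level network metrics (degree,
    eigenvector and betweenness centrality, local clustering, density,
    average path length), and tests species differences with data-stream
    swap randomizations of the raw observations and node-label permutation
    t-tests. Includes a seeded synthetic focal-sampling generator with
    species-assortative latent structure so the full pipeline is testable
    without observational data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
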