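Package: sigrev
Title: Connectivity-Map Signature Reversal and Network Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a disease expression profile to drug-treatment profiles by
    rank-based connectivity scoring with permutation significance,
    repressor-weighted pathway activity, degree-weighted network efficacy on a
    protein-interaction backbone, Markov-cluster functional module detection,
    and keyword literature-association statistics. Ships a synthetic-data
    generator that plants disease and reversal structure in every input so the
    whole pipeline is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
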