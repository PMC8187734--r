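Package: domarchnet
Title: Evolving Networks of Protein Domain Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds time-resolved networks of protein domain organization from
    SCOP concise classification strings (ccs) and a phylogenomic chronology of
    relative ages, under five operative connectivity criteria (CX, PX, PAX,
    SPX, SPAX). Provides per-event statistics of preferential attachment
    (log-linear regression slope, discrete power-law maximum likelihood with
    Kolmogorov-Smirnov cutoff selection), randomness (rank version of von
    Neumann's ratio test), and modularity (VOS quality, clustering ratio,
    average clustering coefficient, fast-greedy and Newman-Girvan indices),
    together with Barabasi, Barabasi-Age and Erdos-Renyi control generators,
    hub percentile tables, waterfall and radial layout coordinates, Pajek
    round-tripping, and a synthetic entity-set generator for fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
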