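Package: decoybench
Title: Negative-Data Benchmarks and Recovery Analytics for Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds negative (decoy) data sets for validating virtual
    high-throughput screening pipelines and evaluates any scoring stage with
    replica-aware rank analytics. Two complementary decoy pathways are
    provided: randomization of ligands across noncognate protein structures
    with protein-identity-aware relabeling of accidental cognate pairs, and
    exhaustive enumeration of constitutional isomers of known binders with
    chemical sanity filtering and seeded decoy sampling. Scoring output from
    external docking or molecular dynamics tools is analysed with recovery
    curves, score-at-rank confidence bands, per-compound rank confidence
    intervals, violin summaries of active ranks, and enrichment factors.
    Includes seeded synthetic fixture generators (structure collections with
    controlled protein-identity degeneracy; score tables with planted
    active/decoy separation and per-replica noise) so every analysis step can
    be exercised without external docking runs.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineOB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
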