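Package: tmanet
Title: Gut Metagenome Profiling of TMA-Synthesis Genes, Enrichment and
    Correlation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for mining shotgun-metagenome gene catalogs
    for trimethylamine (TMA) synthesis potential in case-control cohorts.
    Converts mapped-read counts into gene-length-normalized abundances,
    assigns catalog genes to KEGG orthologs/modules and to the four TMA
    enzyme families (CutC, CntA, GrdH, TorA) from tabular alignment hits,
    attributes enzyme genes to taxa with a lowest-common-ancestor rule,
    scores case enrichment with an abundance odds-ratio statistic plus
    Wilcoxon rank-sum tests with Benjamini-Hochberg correction, and builds a
    thresholded Spearman correlation network linking genera, enzyme genes
    and functional features. Ships a synthetic-study generator with planted
    effects so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
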