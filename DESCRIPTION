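Package: npscoloc
Title: Co-Localization and Enrichment Statistics for Chromatin-Bound
    Protein Clusters at Natural Pausing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for asking whether the chromatin-binding
    clusters of different proteins co-localize genome-wide and are enriched
    at natural replication pausing sites (tRNA genes, centromeres,
    replication termination regions) in budding yeast. The co-localization
    score between two cluster sets is the total number of overlapping bases;
    significance is assessed against a Monte-Carlo randomization null that
    preserves per-chromosome cluster counts and lengths, and by a one-tailed
    Fisher's exact test on the genome-wide base-count contingency table.
    Companion modules compute fold enrichment of clusters over random
    binding at annotated feature classes, discrete-feature co-occupancy
    tables across proteins, rule-based classification of psoralen-EM joint
    molecules (forks, bubbles, reversed forks, double Holliday junctions,
    hemicatenanes) from branch-length records, and ChIP-qPCR percent-input
    quantification by the 2^(-dCt) method with unpaired t-tests. A seeded
    synthetic-data generator produces genomes, feature annotations, cluster
    sets with a controllable co-localization parameter, joint-molecule
    records and qPCR tables, so the whole pipeline is testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    optparse
Config/testthat/edition: 3
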