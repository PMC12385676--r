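Package: cnvnetprio
Title: CNV Region Algebra, Interactome Diffusion and Candidate Gene
    Prioritization for Neurodevelopmental Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing candidate genes from
    copy-number variant (CNV) screens in neurodevelopmental disorders.
    Implements BED-convention interval algebra over loss/gain CNV calls
    (merge, shared, unique regions) with gene and lncRNA annotation;
    confidence-filtered protein-protein interactome construction with
    first-neighbor subnetwork extraction and network merging; network
    propagation by heat-kernel diffusion from query gene sets with
    rank- or size-based subnetwork selection; centrality-based gene role
    classification (hubs, provincial hubs, connector/bottleneck genes);
    and dosage-sensitivity-flagged candidate reporting with diagnostic
    yield computation. A seeded synthetic-data generator emulates CNV
    call sets with controlled loss/gain overlap and scale-free-like
    networks with planted topological roles, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
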