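# cnvnetprio

Network-based prioritization of candidate genes from copy-number variant
(CNV) screens in neurodevelopmental disorders (NDD).

Chromosomal microarray testing of patients with unexplained developmental
delay, intellectual disability or autism returns CNV calls — genomic
losses and gains — many of which contain genes of unclear clinical
relevance. This package turns the residual (non-pathogenic-classified)
calls into a ranked candidate-gene report for geneticists and
computational biologists, by combining:

* **Interval algebra** over pooled loss/gain calls (BED convention,
  0-based half-open): per-type merge, per-base intersection (regions seen
  as both loss and gain) and differences (regions unique to each type),
  with gene/lncRNA retrieval by ≥ 1 bp coordinate overlap.
* **Interactome construction** from a scored protein–protein edge list
  (HIPPIE-style dialects supported): edges kept at confidence ≥ 0.63 (the
  HIPPIE medium-confidence cutoff), first-neighbor induced subnetwork
  extraction for a query gene list, and network merging.
* **Network propagation** by the graph heat kernel: `h = exp(-tL) h0`,
  where `L = D - A` is the unweighted Laplacian and `h0` places unit heat
  on the query genes; the top-ranked nodes (e.g. rank cutoff 99 → 100
  genes) form the *smallest* prioritized interactome.
* **Centrality-based role taxonomy** on the selection: degree and exact
  betweenness (thresholded at their means), closeness ("proximity") and
  per-node average shortest path length (thresholded at their medians)
  classify each gene as hub / provincial hub / connector-bottleneck /
  peripheral, and integrated / vulnerable / intermediate.
* **Dosage-sensitivity flags and reporting**: `pHaplo ≥ 0.55` flags
  deletion-sensitive genes, `pTriplo ≥ 0.68` duplication-sensitive ones;
  the report cross-tabulates CNV origin, smallest-interactome membership,
  disease-panel membership, roles and flags, and computes the cohort
  diagnostic yield (pathogenic findings / QC-passing samples, whole
  percent).

A seeded synthetic-data generator (`synthetic_config()`, `gen_*`)
emulates CNV call sets with controlled loss/gain overlap and
scale-free-like networks with planted hubs, provincial hubs and
bottlenecks, so the entire pipeline is testable with no downloads.

## Worked example

```r
library(cnvnetprio)

cfg <- synthetic_config(seed = 1)       # 30 samples, 160-node interactome
res <- run_synthetic_pipeline(cfg)      # intervals -> network -> diffusion -> report

res$report
#> <candidate_report> 88 CNV genes | 37 in smallest interactome | 6 also in panel
#>    symbol cnv_origin in_smallest in_ndd_panel       hub_axis integration_axis ...
#> 1   G0064       gain        TRUE        FALSE            hub       integrated
#> 2   G0190       gain        TRUE        FALSE            hub       vulnerable
#> 3   G0018       loss        TRUE        FALSE provincial_hub       vulnerable
#> ...

res$roles_summary
#> <network_summary> mean degree 0.800 | mean betweenness 6.940 | median closeness 0.3261 | median aspl 3.067

compute_yield(9, 29)
#> diagnostic yield: 31% (9/29)
```

Reading the output: 88 protein-coding genes fall in regions unique to one
CNV type; 37 of them survive into the 50-node diffusion-selected
subnetwork, 6 of those are also on the synthetic NDD panel. Each row
carries the gene's topological role (e.g. `hub` = above-mean degree *and*
betweenness), its integration status relative to the network medians, its
dosage scores and the resulting deletion/duplication-sensitivity flags;
`headline_flag` pairs deletion sensitivity with loss CNVs and duplication
sensitivity with gains. `compute_yield(9, 29)` is the cohort-level
diagnostic yield for 9 pathogenic findings among 29 QC-passing samples.

Individual stages are exported (`merge_same_type()`, `shared_regions()`,
`unique_regions()`, `annotate_genes()`, `read_edge_list()`,
`filter_confidence()`, `first_neighbor_subnetwork()`, `heat_diffuse()`,
`select_subnetwork()`, `compute_centralities()`, `classify_roles()`,
`flag_dosage()`, `assemble_candidates()`, ...) and documented; the
vignette `vignettes/cnv-network-prioritization.Rmd` explains the model,
its assumptions, the numerical choices and what the synthetic tests do
and do not demonstrate.

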