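---
title: "From CNV calls to prioritized candidate genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CNV calls to prioritized candidate genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvnetprio)
```

## The problem this package addresses

Chromosomal microarray screens in patients with neurodevelopmental
disorders (NDD) and autism spectrum disorder return copy-number variants
(CNVs) — genomic losses and gains — whose clinical significance is often
unclear. After the clearly pathogenic calls are set aside, the remaining
variants still harbor candidate genes, and the question becomes: *which
genes inside the residual CNV regions are most likely to matter for
neurodevelopment?*

`cnvnetprio` implements a network-based answer as a tested, reusable
pipeline:

1. **Interval algebra.** Loss calls and gain calls are pooled across
   samples and merged per type. The per-base intersection gives the regions
   seen as *both* loss and gain; the per-base differences give the regions
   unique to each type. Downstream analysis uses the unique regions, and
   genes and lncRNAs are retrieved by coordinate overlap.
2. **Interactome construction.** A scored protein–protein interaction
   edge list (HIPPIE-style) is filtered at a confidence cutoff (default
   0.63, the HIPPIE medium-confidence threshold); the subnetwork induced by
   the CNV-derived genes and their first neighbors forms the working
   interactome. Independent subnetworks can be merged (node union, edge
   union, maximum confidence on duplicates).
3. **Network propagation.** Unit heat placed on the query genes is spread
   by the heat kernel `exp(-tL)` of the unweighted graph Laplacian; the
   top-ranked nodes form the *smallest* prioritized interactome.
4. **Role classification.** Degree, betweenness, closeness ("proximity")
   and per-node average shortest path length are computed on the selection,
   summarized network-wide, and each gene is labelled *hub*, *provincial
   hub*, *connector/bottleneck* or *peripheral*, and *integrated*,
   *vulnerable* or *intermediate*.
5. **Candidate report.** CNV-derived genes are cross-referenced with
   smallest-interactome membership, a curated NDD panel and
   dosage-sensitivity scores (pHaplo/pTriplo flags), and the cohort
   diagnostic yield is computed.

## Interval semantics

Coordinates are 0-based half-open (BED). Merging coalesces overlapping
*and book-ended* intervals, matching the default behavior of the standard
BED merge tooling; `[0,100)` and `[100,200)` become `[0,200)`. A gene is
annotated to a region when they overlap by at least 1 bp, so half-open
adjacency is never an overlap. Inputs quoted in 1-based inclusive
coordinates (as clinical tables usually are) are converted on read via
`read_cnv_bed(..., one_based = TRUE)`.

One wording subtlety is resolved in favor of set theory: subtraction of
merged loss and gain sets yields the regions *unique* to each type, and
intersection yields the regions detected as *both*; the package names its
outputs accordingly (`unique_loss`, `unique_gain`, `shared`) and tests the
partition law `unique_loss ⊎ unique_gain ⊎ shared = loss ∪ gain` on every
randomized case.

## Confidence filtering

"Filtering at 0.63" is implemented as *retaining* edges with confidence
≥ 0.63 and dropping the rest. 0.63 is the published medium-confidence
cutoff of the HIPPIE resource; the opposite reading (discarding everything
at or above medium confidence) would leave a near-empty network and is not
a usable interactome. Isolated nodes do not count toward a filtered
network's size. First-neighbor extraction returns the full *induced*
subgraph (neighbor–neighbor edges included); a query-incident-edges-only
variant is available via `edges = "incident"`.

## Heat diffusion: model and numerics

Propagation solves the heat equation on the graph: `h(t) = exp(-tL) h0`
with `L = D − A` the unweighted Laplacian and `h0` the indicator of the
seed set. Because `L` has zero row sums, total heat is conserved, and as
`t → ∞` heat equilibrates to `(#seeds in component)/|component|` within
each connected component.

* **Time parameter.** `time_t` defaults to 0.1, the default of the
  network-diffusion app this step is modelled on. Larger `t` smooths heat
  over wider neighborhoods; the cited tooling does not expose a principled
  choice, so `t` is an explicit config field.
* **Evaluation.** The kernel action is computed by uniformization: with
  `μ = max degree`, `P = I − L/μ` is nonnegative with unit row sums and
  `exp(-tL) h0 = Σ_k e^{-tμ} (tμ)^k/k! · P^k h0`. All terms are
  nonnegative, so truncating when the remaining Poisson tail mass falls
  below `1e-10` of the total heat bounds the error directly. For `tμ > 20`
  the time interval is split into segments so `e^{-tμ}` never underflows.
  Tests verify agreement with a dense matrix exponential to `1e-8` on
  random graphs and exact behavior in the `t → 0` and `t → ∞` limits.
* **Weights.** Diffusion runs on topology by default (confidences are
  ignored), matching the modelled tool; a confidence-weighted Laplacian is
  available behind `weighted = TRUE` and is an extension, not the default.
* **Ranks and ties.** Ranks are 0-based by descending heat with ties
  broken lexicographically by node name, so the rank vector is always a
  permutation and selection is deterministic. A heat tie that straddles
  the selection boundary is reported (`tie_at_boundary`).
* **Selection.** `rank_cutoff` mode selects all nodes with rank ≤ cutoff
  (cutoff 99 → 100 genes, the "smallest interactome" convention);
  `output_size` mode selects a fixed number of top-heat nodes, by default
  retaining the seeds in addition (`include_query = TRUE`), because a
  propagated candidate network is read together with the query that
  produced it. The published description of the corresponding analysis
  does not state how its diffusion output size maps to its final network
  size, so both knobs are exposed rather than hard-coding one
  interpretation.

## Centrality summaries and role taxonomy

Degree and betweenness (exact, unnormalized, each unordered pair counted
once) are summarized by their **mean**; closeness and per-node average
shortest path length by their **median**. Using the mean for the two
heavy-tailed measures is statistically counterintuitive (means chase the
very outliers a robust summary would resist), but it is the stated
procedure of the workflow this package operationalizes, so it is the
default; `summarize_centralities(median_for_all = TRUE)` switches every
threshold to the median.

Closeness here is the within-component variant
`(#reachable)/(Σ distances)` and aspl is the mean distance to reachable
nodes; both are undefined (`NA`, never 0) for singletons, which are
excluded from the medians and always classified `intermediate` with a
flag. Threshold comparisons use `≥`/`≤` at the boundary: the source
taxonomy gives directions ("high"/"low"), not strict inequalities, and an
inclusive boundary makes the vertex-transitive case (every node equal to
the summary) classify as hub-like rather than peripheral.

The role grid is:

| degree vs mean | betweenness vs mean | label |
|---|---|---|
| ≥ | ≥ | hub |
| ≥ | < | provincial hub |
| < | ≥ | connector/bottleneck |
| < | < | peripheral |

and independently, closeness ≥ median with aspl ≤ median is *integrated*,
closeness < median with aspl > median is *vulnerable*, anything else
*intermediate*. Labels are scale-free in betweenness: rescaling all
betweenness values rescales the mean identically.

## Dosage flags and the candidate report

`flag_dosage()` sets `haplo_flag` when `pHaplo ≥ 0.55` and `triplo_flag`
when `pTriplo ≥ 0.68` (boundary inclusive). These defaults are the
operating points used for candidate selection in the cohort analysis this
pipeline reproduces; the more commonly published strict cutoffs
(0.86/0.94) ship as the `"published"` preset. The report's headline column
pairs deletion sensitivity with loss CNVs and duplication sensitivity with
gain CNVs, while both flags are always computed and reported. Missing
scores never flag and are audited in `missing_score`.

`compute_yield()` rounds half away from zero to a whole percent
(9/29 → 31%). `assemble_candidates()` reports inclusion–exclusion
arithmetic for the smallest interactome
(`|CNV ∩ S| + |panel ∩ S| − |both ∩ S|`), and its outputs are byte-stable:
a fixed input written twice produces identical TSV and JSON.

## What the synthetic generator emulates — and what it does not

Every stage is testable offline through `synthetic_config()` and the
`gen_*` family. Design choices, fixed once:

* **Cohort scale.** 30 samples, 3 loss + 3 gain calls each, two 100-kb
  chromosomes carrying 200 disjoint genes (80% protein-coding). Small
  chromosomes keep the generator's internal per-base ground-truth oracle
  exact; the interval code itself is coordinate-scale-independent.
* **Controlled overlap.** Loss calls are drawn in the first 45% of each
  chromosome and free gain calls in the last 45%; a fraction
  `loss_gain_overlap_frac` (default 0.25) of gain calls are exact copies
  of loss intervals. Overlap 0 therefore guarantees an empty shared set
  and overlap 1 empty unique sets, giving sharp edge-case tests.
* **Planted topology.** Two preferential-attachment communities (attach
  `m = 2`, 160 nodes) joined only through planted bottleneck nodes, each
  attached by two edges per community to the highest-degree community
  cores — this funnels cross-community shortest paths through the
  bottleneck while keeping its degree low. Planted hubs receive extra
  edges to 8% of nodes graph-wide; provincial hubs to 30% of their own
  community. With these defaults, planted hubs classify as `hub` and
  planted bottlenecks as `connector_bottleneck` in well over 90% of seeded
  replicates, and bottlenecks top the betweenness/degree ratio among
  non-hub nodes.
* **Confidences.** Beta(4, 2) (mean 2/3), so the 0.63 filter removes a
  nontrivial minority of edges rather than almost none or almost all.
* **Seed discipline.** One master seed; each component (gene models,
  calls, network, scores, panel) derives a fixed substream, so adding a
  component never changes another's draw, and identical configurations
  are byte-identical end to end.

What the generator does **not** emulate: array probe intensities or CNV
calling, linkage between gene density and CNV location, realistic
gene-length and confidence distributions, identifier aliasing, or
tissue-specific expression. Passing tests therefore demonstrate the
correctness of the algebra, propagation and classification machinery —
not that any particular biological discovery would replicate.

## Validation strategy and problem sizes

The test suite validates each stage against an independent brute-force
oracle, at sizes chosen so the oracles are exact:

* interval algebra against per-base boolean arrays on 200 randomized call
  sets over ≤ 9-kb chromosomes, plus the bp-count partition identity;
* diffusion against a dense matrix exponential (`Matrix::expm`) to `1e-8`
  on random graphs of up to 12 nodes, plus conservation and both time
  limits;
* betweenness against exhaustive simple-path enumeration on 200 random
  graphs of up to 8 nodes;
* planted-role recovery over 50 seeded replicates of the default
  generator;
* end-to-end determinism: the full pipeline written twice from one
  configuration compares byte-identical.

## Known limitations

* Symbol matching is exact after uppercasing; no alias or ortholog
  resolution.
* The published network sizes of the cohort analysis that motivated this
  pipeline (custom interactome, merged NDD interactome) depend on
  third-party databases and web services at specific versions and cannot
  be recomputed from code alone; the package validates the operations,
  not those historical snapshots.
* Diffusion is the only propagation kernel; random-walk-with-restart is a
  possible future alternative.
* Betweenness is exact, so very large networks (≫ 10^5 edges) will be
  slow; the intended scale is the few-thousand-node working interactomes
  of a cohort analysis.

## A worked run

```{r pipeline}
cfg <- synthetic_config(seed = 1)
res <- run_synthetic_pipeline(cfg)
res$report
res$roles_summary
table(res$roles$hub_axis)
compute_yield(9, 29)
```
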