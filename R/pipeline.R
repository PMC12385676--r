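#' Run the full synthetic CNV-to-candidate pipeline
#'
#' End-to-end driver over a synthetic data set, mirroring the analysis
#' stages on real data:
#' 1. generate gene models, CNV calls, a scored network, a disease panel
#'    and dosage scores from `cfg`;
#' 2. merge loss and gain calls, derive shared/unique regions, and annotate
#'    the unique regions with genes (downstream uses unique regions only);
#' 3. filter the network at the confidence threshold and extract the
#'    first-neighbor subnetwork of the CNV genes;
#' 4. diffuse heat from the CNV genes plus panel genes and select the
#'    top-ranked subnetwork;
#' 5. compute centralities and role labels on the selection;
#' 6. assemble the flagged candidate report.
#'
#' All randomness derives from `cfg$seed`, so a fixed configuration yields
#' byte-identical outputs.
#'
#' @param cfg A [synthetic_config()].
#' @param diff_cfg A [diffusion_config()]; its selection is applied to the
#'   diffusion result.
#' @param confidence_threshold Edge-confidence cutoff for the base network.
#' @param out_dir Optional directory; when given, the region BEDs and the
#'   candidate report (TSV + JSON) are written there.
#' @return A list with elements `regions` (merged/shared/unique region
#'   sets), `cnv_genes`, `network` (filtered), `subnetwork` (first-neighbor),
#'   `heat`, `selection`, `profiles`, `roles_summary`, `roles`, `report`.
#' @export
#' @examples
#' res <- run_synthetic_pipeline(synthetic_config(seed = 1))
#' res$report$summary$n_cnv_in_smallest
run_synthetic_pipeline <- function(cfg,
                                   diff_cfg = diffusion_config(
                                     selection_mode = "rank_cutoff",
                                     selection_value = 49L),
                                   confidence_threshold = 0.63,
                                   out_dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gm <- gen_gene_models(cfg)
  sim <- gen_cnv_callset(cfg)
  netsim <- gen_network(cfg)
  panel <- gen_ndd_panel(gm$symbol, seed = cfg$seed)
  dosage <- gen_dosage_table(gm$symbol, seed = cfg$seed)

  merged_loss <- merge_same_type(sim$calls, "loss")
  merged_gain <- merge_same_type(sim$calls, "gain")
  shared <- shared_regions(merged_loss, merged_gain)
  uniq <- unique_regions(merged_loss, merged_gain)

  loss_genes <- annotate_genes(uniq$unique_loss, gm,
                               gene_type_filter = "protein_coding")$genes
  gain_genes <- annotate_genes(uniq$unique_gain, gm,
                               gene_type_filter = "protein_coding")$genes
  # a gene hit by both unique-loss and unique-gain regions keeps the loss
  # origin (deletions reported first)
  cnv_genes <- rbind(
    data.frame(symbol = loss_genes, cnv_origin = "loss",
               stringsAsFactors = FALSE),
    data.frame(symbol = setdiff(gain_genes, loss_genes), cnv_origin = "gain",
               stringsAsFactors = FALSE)
  )

  net <- filter_confidence(netsim$network, confidence_threshold)
  sub <- first_neighbor_subnetwork(net, cnv_genes$symbol)

  seeds <- intersect(union(cnv_genes$symbol, panel),
                     network_nodes(net))
  heat <- heat_diffuse(net, seeds, diff_cfg)
  sel <- select_subnetwork(net, heat, diff_cfg)

  profiles <- compute_centralities(sel$network)
  summ <- summarize_centralities(profiles)
  roles <- classify_roles(profiles, summ)

  report <- assemble_candidates(cnv_genes, sel$genes, panel,
                                roles = roles,
                                dosage = flag_dosage(dosage))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_region_bed(merged_loss, file.path(out_dir, "merged_loss.bed"))
    write_region_bed(merged_gain, file.path(out_dir, "merged_gain.bed"))
    write_region_bed(shared, file.path(out_dir, "shared.bed"))
    write_region_bed(uniq$unique_loss, file.path(out_dir, "unique_loss.bed"))
    write_region_bed(uniq$unique_gain, file.path(out_dir, "unique_gain.bed"))
    write_report(report, out_dir)
  }
  list(regions = list(merged_loss = merged_loss, merged_gain = merged_gain,
                      shared = shared, unique_loss = uniq$unique_loss,
                      unique_gain = uniq$unique_gain),
       cnv_genes = cnv_genes, network = net, subnetwork = sub,
       heat = heat, selection = sel, profiles = profiles,
       roles_summary = summ, roles = roles, report = report)
}
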