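#' Run the full analysis chain on fixture or user inputs
#'
#' Executes the dry-bench pipeline: motif scan (when regions are supplied),
#' circuit census on both species' direct networks, knockout prediction and
#' concordance against the packaged reporter observations, and the
#' cross-species conservation partition. Outputs are written as TSV files
#' under `out_dir` when given; a machine-readable summary list is returned
#' either way. Runs are deterministic for a fixed `seed`.
#'
#' @param regions Optional list of `promoter_region` objects to scan.
#' @param motif_set Motifs for the scan stage (default [nitrate_motifs()]).
#' @param peaks Optional peak set for open-chromatin flags.
#' @param net_at,net_sl Signed networks (default: packaged fixtures).
#' @param map Ortholog map (default: packaged fixture).
#' @param p_cutoff,q_cutoff,max_gap Scan thresholds.
#' @param seed RNG seed recorded in the summary.
#' @param out_dir Optional output directory.
#' @return List with elements `edge_counts`, `census`, `concordance_at`,
#'   `concordance_sl`, `conservation`, and (when regions were scanned)
#'   `hits`.
#' @export
run_pipeline <- function(regions = NULL, motif_set = nitrate_motifs(),
                         peaks = NULL, net_at = circuit_fixture("at_direct"),
                         net_sl = circuit_fixture("sl_direct"),
                         map = ortholog_fixture(), p_cutoff = 1e-4,
                         q_cutoff = 0.05, max_gap = 14, seed = 1L,
                         out_dir = NULL) {
  set.seed(seed)
  res <- list(seed = seed)
  if (!is.null(regions)) {
    scan <- call_candidate_sites(regions, motif_set, peaks = peaks,
                                 p_cutoff = p_cutoff, q_cutoff = q_cutoff,
                                 max_gap = max_gap)
    res$hits <- scan$hits
    res$arf_pairs <- scan$arf_pairs
  }
  at_dir <- direct_network(net_at)
  sl_dir <- direct_network(net_sl)
  res$edge_counts <- c(at_direct = nrow(at_dir$edges),
                       sl_direct = nrow(sl_dir$edges))
  res$census <- list(
    at_autoregulation = find_autoregulation(at_dir),
    at_ffls = enumerate_ffls(at_dir),
    sl_ffls = enumerate_ffls(sl_dir))
  for (sp in c("At", "Sl")) {
    net <- if (sp == "At") net_at else net_sl
    px <- parot_genotypes(sp)
    preds <- lapply(px$genotypes, predict_genotype, net = net)
    obs <- px$observations
    res[[paste0("concordance_", tolower(sp))]] <-
      compare_to_observations(preds, obs)
  }
  canA <- canonicalize(at_dir, map, species = "At")
  canB <- canonicalize(sl_dir, map, species = "Sl")
  res$conservation <- intersect_networks(canA, canB)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$hits)) {
      write_hits(res$hits, file.path(out_dir, "candidate_sites.tsv"))
    }
    write_edges(res$census$at_ffls, file.path(out_dir, "at_ffls.tsv"))
    write_concordance(res$concordance_at,
                      file.path(out_dir, "concordance_at.tsv"))
    write_concordance(res$concordance_sl,
                      file.path(out_dir, "concordance_sl.tsv"))
    write_edges(res$conservation$conserved,
                file.path(out_dir, "conserved_edges.tsv"))
  }
  res
}
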