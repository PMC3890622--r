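#' End-to-end recovery benchmark on a simulated universe
#'
#' Simulates a genome universe, runs the full delineation pipeline on
#' it — all-vs-all similarity network, connected-component clustering
#' at the conservative and relaxed thresholds, seeded breadth-first
#' retrieval of the marker families, synteny network and lineage
#' inference — and scores the result against the simulator's ground
#' truth. Traversal is seeded with one known exemplar per marker family
#' (the counterpart of starting from a functionally characterized
#' protein).
#'
#' @param config A [simulation_config()].
#' @param cutoff_exponent Retrieval threshold exponent (default -15).
#' @param neighbour_exponent Conservative clustering exponent
#'   (default -30).
#' @param W Window half-width (default 15).
#' @return A list: `universe`, `network`, `lineages`, and one-row
#'   tibbles `lineage_scores` (pairwise precision/recall/F1, ARI vs
#'   truth lineages over marker genes) and `family_scores` (same
#'   metrics for the conservative clustering vs truth families over all
#'   genes).
#' @export
evaluate_recovery <- function(config, cutoff_exponent = -15,
                              neighbour_exponent = -30, W = 15) {
  u <- simulate_universe(config)
  net <- all_vs_all(u$proteins,
                    cutoff_exponent = max(cutoff_exponent, -12))
  cl_cons <- global_clusters(net, neighbour_exponent)
  cl_relax <- global_clusters(net, cutoff_exponent)

  truth_m <- filter(u$truth, startsWith(.data$family, "fam"))
  seeds <- truth_m |>
    group_by(.data$family) |>
    summarise(seed = min(.data$gene_id), .groups = "drop")
  cnet <- constrain(net, cutoff_exponent)
  queries <- unique(unlist(lapply(seeds$seed, function(s)
    traverse(cnet, s))))

  snet <- build_synteny_network(
    queries, u$annotation, neighbour_clusters = cl_cons,
    query_clusters = cl_cons, relaxed_clusters = cl_relax,
    W = W, net = net)
  lineages <- infer_lineages(snet)

  lineage_scores <- score_recovery(
    lineages, transmute(truth_m, gene_id = .data$gene_id,
                        label = .data$lineage))
  family_scores <- score_recovery(
    cl_cons, transmute(u$truth, gene_id = .data$gene_id,
                       label = .data$family))
  list(universe = u, network = net, lineages = lineages,
       queries = queries,
       lineage_scores = lineage_scores, family_scores = family_scores)
}
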