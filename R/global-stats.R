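#' Per-cluster identity/similarity summary from global alignments
#'
#' Aligns every pair of members within each cluster with the global
#' aligner ([needleman_wunsch()], needle-default penalties) and reports
#' the minimum and mean percent identity and similarity. Clusters with a
#' single member have no pair to align and are reported as `NA`
#' (rendered `-` by [write_cluster_summary()]).
#'
#' @param clusters Tibble `protein_id`, `cluster_label` (e.g. from
#'   [global_clusters()] or a phylogenetic-cluster table).
#' @param records Protein records tibble covering every assigned ID.
#' @param full_size_only When `TRUE`, restrict to records flagged
#'   full-size in `topology`; requires the `topology` argument.
#' @param topology Optional tibble from [topology_table()].
#' @param scheme Scoring scheme for the global alignments.
#' @return Tibble `cluster`, `n_members`, `min_identity`,
#'   `mean_identity`, `min_similarity`, `mean_similarity`.
#' @export
cluster_summary <- function(clusters, records, full_size_only = FALSE,
                            topology = NULL,
                            scheme = scoring_scheme("BLOSUM62", 10.0, 0.5)) {
  stopifnot(all(clusters$protein_id %in% records$id))
  if (full_size_only) {
    if (is.null(topology)) abort("full_size_only requires a topology table")
    keep <- topology$protein_id[topology$full_size]
    clusters <- filter(clusters, .data$protein_id %in% keep)
  }
  seqs <- setNames(records$sequence, records$id)
  clusters |>
    group_by(cluster = .data$cluster_label) |>
    group_modify(function(df, key) {
      ids <- sort(df$protein_id)
      n <- length(ids)
      if (n < 2) {
        return(tibble(n_members = n, min_identity = NA_real_,
                      mean_identity = NA_real_, min_similarity = NA_real_,
                      mean_similarity = NA_real_))
      }
      pairs <- utils::combn(ids, 2)
      stats <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
        al <- needleman_wunsch(seqs[[pairs[1, k]]], seqs[[pairs[2, k]]],
                               scheme)
        tibble(identity = al$identity_pct, similarity = al$similarity_pct)
      })
      tibble(n_members = n,
             min_identity = min(stats$identity),
             mean_identity = mean(stats$identity),
             min_similarity = min(stats$similarity),
             mean_similarity = mean(stats$similarity))
    }) |>
    ungroup()
}

#' Write a cluster summary as TSV, printing singleton clusters as "-"
#'
#' @param summary Tibble from [cluster_summary()].
#' @param path Output path.
#' @param digits Decimal places for the percentage columns (default 1).
#' @return `path`, invisibly.
#' @export
write_cluster_summary <- function(summary, path, digits = 1) {
  fmt <- function(x) ifelse(is.na(x), "-", formatC(x, format = "f",
                                                   digits = digits))
  out <- summary |>
    mutate(across(c("min_identity", "mean_identity",
                    "min_similarity", "mean_similarity"), fmt))
  readr::write_tsv(out, path)
  invisible(path)
}
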