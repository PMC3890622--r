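#' Extract the gene neighbourhood window of a query gene
#'
#' Up to `W` genes on each side of the query in gene order (ordinals),
#' never crossing a contig boundary. Offsets are signed gene-rank
#' distances from the query; strand plays no role in window membership.
#'
#' @param annotation Annotation tibble (see [read_annotation()]); may
#'   hold several strains, in which case contigs are scoped per strain.
#' @param gene_id Query gene ID present in the annotation.
#' @param W Window half-width in genes (default 15 per side).
#' @return Tibble `neighbour`, `offset` with a `query` attribute.
#' @export
extract_window <- function(annotation, gene_id, W = 15) {
  hit <- annotation[annotation$gene_id == gene_id, ]
  if (nrow(hit) == 0) abort(paste0("unknown gene: ", gene_id))
  scope <- annotation
  if ("strain" %in% names(annotation)) {
    scope <- annotation[annotation$strain == hit$strain[1], ]
  }
  ctg <- scope[scope$contig == hit$contig[1], ]
  off <- ctg$ordinal - hit$ordinal[1]
  keep <- off != 0L & abs(off) <= W
  out <- tibble(neighbour = ctg$gene_id[keep], offset = as.integer(off[keep])) |>
    arrange(.data$offset)
  attr(out, "query") <- gene_id
  out
}

# windows for many queries at once: tibble(query, neighbour, offset)
windows_table <- function(annotation, queries, W = 15) {
  missing <- setdiff(queries, annotation$gene_id)
  if (length(missing) > 0) {
    abort(paste0("unknown gene(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  key <- if ("strain" %in% names(annotation)) {
    paste(annotation$strain, annotation$contig)
  } else {
    annotation$contig
  }
  ann <- annotation |> mutate(.ctg = key)
  q <- ann |> filter(.data$gene_id %in% queries) |>
    select(query = "gene_id", .ctg = ".ctg", q_ord = "ordinal")
  ann |>
    select(neighbour = "gene_id", .ctg = ".ctg", n_ord = "ordinal") |>
    inner_join(q, by = ".ctg", relationship = "many-to-many") |>
    mutate(offset = as.integer(.data$n_ord - .data$q_ord)) |>
    filter(.data$offset != 0L, abs(.data$offset) <= W) |>
    select("query", "neighbour", "offset")
}

#' Shared homologous neighbour pairs between two windows
#'
#' The synteny criterion: two query genes share a neighbour pair when a
#' gene in one window and a distinct gene in the other belong to the
#' same sequence cluster. Each evidence row carries the three strength
#' criteria: closeness (how near the pair sits to the queries), the
#' pairwise E-value of the connecting neighbours (when a similarity
#' network is supplied), and the size of the shared cluster (small
#' clusters make a chance shared pair unlikely).
#'
#' @param win_a,win_b Windows from [extract_window()].
#' @param clusters Cluster assignment tibble (`protein_id`,
#'   `cluster_label`; a `cluster_size` column is recomputed if absent).
#'   Genes absent from the table are treated as singleton clusters and
#'   therefore can never form evidence.
#' @param exclude_cluster Optional cluster label to exclude (normally
#'   the query genes' own cluster, so tandem arrays of the query family
#'   do not certify their own synteny).
#' @param net Optional [similarity_network()] used to look up the pair
#'   E-value between connecting neighbours.
#' @return Evidence tibble: `neighbour_a`, `offset_a`, `neighbour_b`,
#'   `offset_b`, `shared_cluster`, `cluster_size`, `pair_evalue`,
#'   `closeness`.
#' @export
shared_pairs <- function(win_a, win_b, clusters, exclude_cluster = NULL,
                         net = NULL) {
  lab <- setNames(clusters$cluster_label, clusters$protein_id)
  size <- if ("cluster_size" %in% names(clusters)) {
    setNames(clusters$cluster_size, clusters$cluster_label)
  } else {
    tab <- table(clusters$cluster_label)
    setNames(as.integer(tab), names(tab))
  }
  a <- win_a |> mutate(cl = unname(lab[.data$neighbour])) |> filter(!is.na(.data$cl))
  b <- win_b |> mutate(cl = unname(lab[.data$neighbour])) |> filter(!is.na(.data$cl))
  ev <- inner_join(a, b, by = "cl", suffix = c("_a", "_b"),
                   relationship = "many-to-many") |>
    filter(.data$neighbour_a != .data$neighbour_b)
  if (!is.null(exclude_cluster)) {
    ev <- filter(ev, !.data$cl %in% exclude_cluster)
  }
  ev <- ev |>
    transmute(
      neighbour_a = .data$neighbour_a, offset_a = .data$offset_a,
      neighbour_b = .data$neighbour_b, offset_b = .data$offset_b,
      shared_cluster = .data$cl,
      cluster_size = as.integer(unname(size[.data$cl])),
      closeness = pmax(abs(.data$offset_a), abs(.data$offset_b))
    )
  ev$pair_evalue <- if (!is.null(net)) {
    lookup_evalue(net, ev$neighbour_a, ev$neighbour_b)
  } else {
    NA_real_
  }
  ev |> select("neighbour_a", "offset_a", "neighbour_b", "offset_b",
               "shared_cluster", "cluster_size", "pair_evalue", "closeness")
}

lookup_evalue <- function(net, a, b) {
  key <- paste(pmin(a, b), pmax(a, b))
  ekey <- paste(net$edges$from, net$edges$to)
  net$edges$evalue[match(key, ekey)]
}

#' Build the synteny network over a set of query genes
#'
#' Every pair of query genes assigned to the same sequence cluster is
#' tested for shared homologous neighbour pairs; an edge is drawn when
#' at least one pair exists. Neighbour homology is judged against a
#' conservative cluster assignment; when a relaxed assignment is also
#' supplied, pairs found only under it are kept and tagged `relaxed`,
#' mirroring the two-threshold corroboration strategy.
#'
#' @param queries Character vector of query gene IDs.
#' @param annotation Combined annotation tibble covering every query's
#'   genome (with `strain` column).
#' @param neighbour_clusters Conservative cluster assignment for
#'   neighbour genes (`protein_id`, `cluster_label`).
#' @param query_clusters Cluster assignment used to group the queries
#'   themselves (defaults to `neighbour_clusters`).
#' @param relaxed_clusters Optional relaxed assignment for the fallback
#'   pass.
#' @param W Window half-width (default 15).
#' @param net Optional [similarity_network()] for pair E-values.
#' @param exclude_query_cluster Drop evidence whose shared cluster is
#'   the query cluster itself (default `TRUE`).
#' @param heterospecific_only Compare only queries from different
#'   strains (default `FALSE`: within-species paralogs may be linked).
#' @return An object of class `synteny_network`: `queries`,
#'   `query_cluster` (named vector), `edges` (query_a, query_b, support,
#'   min_closeness, best_pair_evalue, min_cluster_size, relaxed),
#'   `evidence` (one row per neighbour pair).
#' @export
build_synteny_network <- function(queries, annotation, neighbour_clusters,
                                  query_clusters = neighbour_clusters,
                                  relaxed_clusters = NULL, W = 15,
                                  net = NULL, exclude_query_cluster = TRUE,
                                  heterospecific_only = FALSE) {
  queries <- sort(unique(queries))
  wins <- windows_table(annotation, queries, W)
  qlab <- setNames(query_clusters$cluster_label, query_clusters$protein_id)[queries]
  qlab[is.na(qlab)] <- queries[is.na(qlab)]   # unassigned queries: singletons
  strain <- if ("strain" %in% names(annotation)) {
    setNames(annotation$strain, annotation$gene_id)[queries]
  } else {
    strain_of(queries)
  }

  pass <- function(cl_table, tag) {
    lab <- setNames(cl_table$cluster_label, cl_table$protein_id)
    size <- cl_table |> count(.data$cluster_label, name = "n")
    sz <- setNames(size$n, size$cluster_label)
    w <- wins |>
      mutate(cl = unname(lab[.data$neighbour])) |>
      filter(!is.na(.data$cl)) |>
      mutate(qcl = unname(qlab[.data$query]))
    ev <- inner_join(w, w, by = c("cl", "qcl"), suffix = c("_a", "_b"),
                     relationship = "many-to-many") |>
      filter(.data$query_a < .data$query_b,
             .data$neighbour_a != .data$neighbour_b)
    if (exclude_query_cluster) ev <- filter(ev, .data$cl != .data$qcl)
    if (heterospecific_only) {
      ev <- filter(ev, strain[.data$query_a] != strain[.data$query_b])
    }
    ev |>
      transmute(query_a = .data$query_a, query_b = .data$query_b,
                neighbour_a = .data$neighbour_a, offset_a = .data$offset_a,
                neighbour_b = .data$neighbour_b, offset_b = .data$offset_b,
                shared_cluster = .data$cl,
                cluster_size = as.integer(unname(sz[.data$cl])),
                closeness = pmax(abs(.data$offset_a), abs(.data$offset_b)),
                relaxed = tag)
  }

  evidence <- pass(neighbour_clusters, FALSE)
  if (!is.null(relaxed_clusters)) {
    conservative_edges <- distinct(evidence, .data$query_a, .data$query_b)
    ev_rel <- pass(relaxed_clusters, TRUE) |>
      anti_join(conservative_edges, by = c("query_a", "query_b"))
    evidence <- bind_rows(evidence, ev_rel)
  }
  evidence$pair_evalue <- if (!is.null(net)) {
    lookup_evalue(net, evidence$neighbour_a, evidence$neighbour_b)
  } else {
    NA_real_
  }
  edges <- if (nrow(evidence) == 0) {
    tibble(query_a = character(0), query_b = character(0),
           support = integer(0), min_closeness = integer(0),
           best_pair_evalue = double(0), min_cluster_size = integer(0),
           relaxed = logical(0))
  } else evidence |>
    group_by(.data$query_a, .data$query_b) |>
    summarise(support = n(),
              min_closeness = min(.data$closeness),
              best_pair_evalue = if (all(is.na(.data$pair_evalue)))
                NA_real_ else min(.data$pair_evalue, na.rm = TRUE),
              min_cluster_size = min(.data$cluster_size),
              relaxed = all(.data$relaxed), .groups = "drop") |>
    arrange(.data$query_a, .data$query_b)
  structure(
    list(queries = queries, query_cluster = qlab, strain = strain,
         edges = edges, evidence = evidence, W = W),
    class = "synteny_network"
  )
}

#' @export
print.synteny_network <- function(x, ...) {
  cat(sprintf("<synteny_network> %d queries, %d edges (%d relaxed), %d evidence pairs\n",
              length(x$queries), nrow(x$edges), sum(x$edges$relaxed),
              nrow(x$evidence)))
  invisible(x)
}

#' @rdname build_synteny_network
#' @param x A `synteny_network`.
#' @param ... Unused.
#' @export
tidy.synteny_network <- function(x, ...) x$edges

#' @rdname build_synteny_network
#' @export
glance.synteny_network <- function(x, ...) {
  lin <- infer_lineages(x)
  tibble(n_queries = length(x$queries), n_edges = nrow(x$edges),
         n_relaxed_edges = sum(x$edges$relaxed),
         n_lineages = length(unique(lin$lineage)))
}

#' Infer gene lineages from a synteny network
#'
#' A lineage is a connected component of the synteny network: the set of
#' genes, across genomes, descending from one ancestral copy as
#' evidenced by conserved neighbourhoods. Queries without any synteny
#' edge form singleton lineages. Labels are the lexicographically
#' smallest member ID.
#'
#' @param snet A [build_synteny_network()] result.
#' @return Tibble `lineage`, `gene_id`, `strain`, `cluster`, one row per
#'   query gene, plus `n_members` and `n_species` per lineage.
#' @export
infer_lineages <- function(snet) {
  comp <- components_from_edges(snet$queries, snet$edges$query_a,
                                snet$edges$query_b)
  comp |>
    transmute(lineage = .data$label, gene_id = .data$id,
              strain = unname(snet$strain[.data$id]),
              cluster = unname(snet$query_cluster[.data$id])) |>
    group_by(.data$lineage) |>
    mutate(n_members = n(), n_species = length(unique(.data$strain))) |>
    ungroup() |>
    arrange(.data$lineage, .data$gene_id)
}

#' Evidence report for synteny edges
#'
#' One row per neighbour-pair evidence item, ordered strongest first:
#' by ascending shared-cluster size (a pair from a rare cluster is
#' unlikely by chance), then ascending closeness.
#'
#' @param snet A `synteny_network`, or its evidence tibble.
#' @return The evidence tibble sorted by (`cluster_size`, `closeness`).
#' @export
edge_report <- function(snet) {
  ev <- if (inherits(snet, "synteny_network")) snet$evidence else snet
  arrange(ev, .data$cluster_size, .data$closeness)
}

#' Export a synteny network to GraphML with edge attributes
#'
#' Edge attributes (`support`, `min_closeness`, `best_pair_evalue`,
#' `min_cluster_size`, `relaxed`) travel with the graph so external
#' viewers can style edges by evidence strength.
#'
#' @param snet A `synteny_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synteny_graphml <- function(snet, path) {
  edges <- snet$edges |> mutate(relaxed = as.integer(.data$relaxed))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = snet$queries,
                          cluster = unname(snet$query_cluster),
                          strain = unname(snet$strain))
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write lineages as TSV
#'
#' @param lineages Tibble from [infer_lineages()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(lineages, path) {
  readr::write_tsv(lineages, path)
  invisible(path)
}
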