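#' Construct a protein similarity network
#'
#' An undirected graph whose nodes are protein IDs and whose edges carry
#' the pairwise E-value of the best local alignment. Edges are stored
#' canonically (`from < to`), self-loops are dropped, and duplicate
#' pairs collapse to their most significant (smallest) E-value.
#'
#' @param edges Tibble with columns `from`, `to`, `evalue` (optionally
#'   `log10_evalue`, `score`).
#' @param nodes Character vector of node IDs; defaults to the IDs seen
#'   in `edges`. Isolated proteins must be listed here to be traversable.
#' @return An object of class `similarity_network`.
#' @export
similarity_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)),
            any(c("evalue", "log10_evalue") %in% names(edges)))
  if (!"log10_evalue" %in% names(edges)) {
    edges$log10_evalue <- log10(edges$evalue)
  }
  if (!"evalue" %in% names(edges)) edges$evalue <- 10^edges$log10_evalue
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  edges <- edges |>
    filter(.data$from != .data$to) |>
    group_by(.data$from, .data$to) |>
    arrange(.data$log10_evalue, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$from, .data$to)
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges),
            class = "similarity_network")
}

#' Build a similarity network from an imported hit table
#'
#' Directional hits (query, subject) collapse to undirected edges
#' weighted by the minimum of the two directional E-values.
#'
#' @param hits Tibble from [read_hit_table()].
#' @param nodes Optional full node set (proteins with no hits).
#' @return A [similarity_network()].
#' @export
network_from_hits <- function(hits, nodes = NULL) {
  similarity_network(
    tibble(from = hits$query, to = hits$subject, evalue = hits$evalue),
    nodes = nodes
  )
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @rdname similarity_network
#' @param x A `similarity_network`.
#' @param ... Unused.
#' @export
tidy.similarity_network <- function(x, ...) x$edges

#' @rdname similarity_network
#' @export
glance.similarity_network <- function(x, ...) {
  n <- length(x$nodes)
  tibble(n_nodes = n, n_edges = nrow(x$edges),
         density = if (n > 1) nrow(x$edges) / (n * (n - 1) / 2) else NA_real_,
         n_components = nrow(distinct(components_table(x), .data$cluster_label)))
}

#' Constrain a similarity network at an E-value threshold
#'
#' Keeps the full node set and only edges with `E <= 10^exponent`.
#' Thresholds are integer exponents because E-values from different
#' alignment engines agree to order of magnitude, not digit-for-digit.
#'
#' @param net A [similarity_network()].
#' @param exponent Integer E-value exponent (e.g. -30).
#' @return The constrained `similarity_network`.
#' @export
constrain <- function(net, exponent) {
  stopifnot(inherits(net, "similarity_network"))
  out <- net
  out$edges <- filter(net$edges, .data$log10_evalue <= exponent)
  out
}

# adjacency list with neighbours sorted lexicographically
adjacency_of <- function(net) {
  adj <- split(c(net$edges$to, net$edges$from),
               c(net$edges$from, net$edges$to))
  lapply(adj, function(v) sort(unique(v)))
}

#' Breadth-first traversal from a seed protein
#'
#' Returns every protein reachable from the seed in the (constrained)
#' network — i.e. the seed's connected component — in breadth-first
#' visit order, neighbours explored in lexicographic ID order.
#'
#' @param net A [similarity_network()].
#' @param seed A node ID present in the network.
#' @return Character vector of reached protein IDs in visit order
#'   (the seed first).
#' @export
traverse <- function(net, seed) {
  stopifnot(inherits(net, "similarity_network"))
  if (!seed %in% net$nodes) abort(paste0("unknown seed node: ", seed))
  adj <- adjacency_of(net)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(seed, TRUE, envir = visited)
  queue <- seed
  order_out <- character(0)
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    order_out <- c(order_out, v)
    for (w in adj[[v]]) {
      if (!exists(w, envir = visited, inherits = FALSE)) {
        assign(w, TRUE, envir = visited)
        queue <- c(queue, w)
      }
    }
  }
  order_out
}

# connected components by repeated BFS over an edge list; label =
# lexicographically smallest member id. This is the package's own
# traversal core; igraph is used only for file export (and as an
# independent oracle in the test suite).
components_from_edges <- function(nodes, from, to) {
  nodes <- sort(unique(c(nodes, from, to)))
  adj <- split(c(to, from), c(from, to))
  adj <- lapply(adj, unique)
  comp <- setNames(rep(NA_character_, length(nodes)), nodes)
  for (v in nodes) {              # nodes sorted => label is smallest member
    if (!is.na(comp[[v]])) next
    queue <- v
    comp[[v]] <- v
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[u]]
      nb <- nb[is.na(comp[nb])]
      if (length(nb) > 0) {
        comp[nb] <- v
        queue <- c(queue, nb)
      }
    }
  }
  tibble(id = nodes, label = unname(comp))
}

components_table <- function(net) {
  components_from_edges(net$nodes, net$edges$from, net$edges$to) |>
    rename(protein_id = "id", cluster_label = "label") |>
    add_count(.data$cluster_label, name = "cluster_size")
}

#' Cluster every protein at an E-value threshold
#'
#' Families are the connected components of the network constrained at
#' `10^exponent`; every node (including isolated proteins) receives
#' exactly one label, canonicalised to the lexicographically smallest
#' member ID so outputs are diff-stable.
#'
#' @param net A [similarity_network()].
#' @param exponent Integer E-value exponent.
#' @return A tibble `protein_id`, `cluster_label`, `cluster_size`.
#' @export
global_clusters <- function(net, exponent) {
  components_table(constrain(net, exponent))
}

#' Sweep traversal across a range of E-value thresholds
#'
#' For each exponent, the network is constrained and traversed from the
#' seed; the profile of retrieved counts against thresholds reveals the
#' plateaus ("clustering ranges") at which family membership is stable.
#' Counts are non-decreasing in the exponent because relaxing the
#' threshold only adds edges.
#'
#' @param net A [similarity_network()].
#' @param seed Seed protein ID.
#' @param exponents Ascending integer exponents (default `-30:-12`).
#' @return A tibble of class `threshold_profile` with columns
#'   `exponent`, `retrieved`, plus a `seed` attribute.
#' @export
sweep_thresholds <- function(net, seed, exponents = -30:-12) {
  stopifnot(all(diff(exponents) > 0))
  counts <- vapply(exponents,
                   function(e) length(traverse(constrain(net, e), seed)),
                   integer(1))
  out <- tibble(exponent = as.integer(exponents), retrieved = counts)
  attr(out, "seed") <- seed
  class(out) <- c("threshold_profile", class(out))
  out
}

#' Detect clustering ranges in a threshold profile
#'
#' A clustering range is a maximal run of consecutive exponents over
#' which the retrieved count is constant (within `tolerance`); the
#' ranges partition the profile exactly. Long ranges signal thresholds
#' at which family membership is robust.
#'
#' @param profile A [sweep_thresholds()] result (or any tibble with
#'   `exponent`, `retrieved`).
#' @param tolerance Maximum count drift absorbed within one range
#'   (default 0: exact equality).
#' @return Tibble `exponent_lo`, `exponent_hi`, `count` (count at the
#'   range start), ordered by exponent.
#' @export
detect_ranges <- function(profile, tolerance = 0) {
  stopifnot(nrow(profile) > 0)
  ex <- profile$exponent
  ct <- profile$retrieved
  brk <- c(TRUE, abs(diff(ct)) > tolerance | diff(ex) != 1L)
  grp <- cumsum(brk)
  tibble(exponent_lo = as.integer(tapply(ex, grp, min)),
         exponent_hi = as.integer(tapply(ex, grp, max)),
         count = as.integer(tapply(ct, grp, function(v) v[1]))) |>
    arrange(.data$exponent_lo)
}

#' Plot a threshold-sweep profile
#'
#' Step plot of sequences retrieved against E-value exponent, the
#' standard way to visualise clustering ranges.
#'
#' @param object A `threshold_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$exponent, y = .data$retrieved)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(
      x = "E-value threshold exponent (E = 10^x)",
      y = "sequences retrieved",
      title = paste0("Threshold sweep",
                     if (!is.null(attr(object, "seed")))
                       paste0(" from seed ", attr(object, "seed")))
    ) +
    ggplot2::theme_minimal()
}

# igraph view of a network, used by the exporters
as_igraph_net <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  g
}

#' Export a similarity network to GraphML
#'
#' @param net A [similarity_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph_net(net), path, format = "graphml")
  invisible(path)
}

#' Export a network in SIF (simple interaction format)
#'
#' One `source similarity target` line per edge; isolated nodes are
#' written as single-column lines so the node set round-trips.
#'
#' @param net A [similarity_network()] (or `synteny_network`).
#' @param path Output path.
#' @param relation Interaction label (default `"similarity"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path, relation = "similarity") {
  edges <- if (inherits(net, "synteny_network")) net$edges else net$edges
  from <- if ("query_a" %in% names(edges)) edges$query_a else edges$from
  to <- if ("query_b" %in% names(edges)) edges$query_b else edges$to
  lines <- sprintf("%s\t%s\t%s", from, relation, to)
  nodes <- if (inherits(net, "synteny_network")) net$queries else net$nodes
  isolated <- setdiff(nodes, c(from, to))
  readr::write_lines(c(lines, isolated), path)
  invisible(path)
}

#' Write a cluster assignment as TSV
#'
#' @param clusters Tibble from [global_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(clusters, path)
  invisible(path)
}
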