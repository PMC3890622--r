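test_that("windows truncate at contig ends and never cross contigs", {
  ann <- tiny_annotation(40, contigs = 2)
  first <- ann$gene_id[ann$contig == "ctg1"][1]
  w <- extract_window(ann, first, W = 15)
  expect_true(all(w$offset > 0))           # nothing to the left
  expect_equal(nrow(w), 15)
  mid <- ann$gene_id[ann$contig == "ctg1"][20]
  w <- extract_window(ann, mid, W = 15)
  expect_equal(nrow(w), 30)                # fifteen per side
  expect_true(all(w$neighbour %in% ann$gene_id[ann$contig == "ctg1"]))
  expect_error(extract_window(ann, "nope"), "unknown gene")
})

test_that("a single-gene contig yields an empty window", {
  ann <- annotate_loci(tibble::tibble(
    gene_id = "spaa_solo", contig = "c9", start = 1L, end = 10L,
    strand = "+", strain = "spaa"))
  expect_equal(nrow(extract_window(ann, "spaa_solo")), 0)
})

test_that("shared_pairs finds cross-window pairs by shared cluster", {
  win_a <- tibble::tibble(neighbour = c("a1", "a2"), offset = c(-2L, 3L))
  win_b <- tibble::tibble(neighbour = c("b1", "b2"), offset = c(1L, -5L))
  clusters <- tibble::tibble(
    protein_id = c("a1", "b1", "a2", "b2"),
    cluster_label = c("X", "X", "Y", "Z"))
  ev <- shared_pairs(win_a, win_b, clusters)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$shared_cluster, "X")
  expect_equal(ev$closeness, 2)            # max(|-2|, |1|)
  # no shared clusters -> empty
  expect_equal(nrow(shared_pairs(win_a, win_b,
                                 dplyr::mutate(clusters,
                                               cluster_label = protein_id))),
               0)
})

test_that("shared_pairs equals exhaustive enumeration on random windows", {
  set.seed(51)
  pool <- sprintf("g%03d", 1:60)
  clusters <- tibble::tibble(
    protein_id = pool,
    cluster_label = paste0("c", sample(1:12, 60, replace = TRUE)))
  for (k in 1:50) {
    na <- sample(5:15, 1)
    nb <- sample(5:15, 1)
    win_a <- tibble::tibble(neighbour = sample(pool, na),
                            offset = sample(c(-15:-1, 1:15), na))
    win_b <- tibble::tibble(neighbour = sample(pool, nb),
                            offset = sample(c(-15:-1, 1:15), nb))
    got <- shared_pairs(win_a, win_b, clusters) |>
      dplyr::arrange(neighbour_a, neighbour_b)
    want <- oracle_shared_pairs(win_a, win_b, clusters) |>
      dplyr::arrange(neighbour_a, neighbour_b)
    expect_equal(got[names(want)], want)
  }
})

test_that("shared_pairs is symmetric up to field swap", {
  set.seed(52)
  pool <- sprintf("g%03d", 1:30)
  clusters <- tibble::tibble(
    protein_id = pool,
    cluster_label = paste0("c", sample(1:6, 30, replace = TRUE)))
  win_a <- tibble::tibble(neighbour = sample(pool, 10),
                          offset = sample(c(-15:-1, 1:15), 10))
  win_b <- tibble::tibble(neighbour = sample(pool, 10),
                          offset = sample(c(-15:-1, 1:15), 10))
  ab <- shared_pairs(win_a, win_b, clusters)
  ba <- shared_pairs(win_b, win_a, clusters)
  expect_equal(nrow(ab), nrow(ba))
  key_ab <- sort(paste(ab$neighbour_a, ab$neighbour_b))
  key_ba <- sort(paste(ba$neighbour_b, ba$neighbour_a))
  expect_equal(key_ab, key_ba)
})

# two strains with homologous gene orders; queries q in the middle
two_strain_setup <- function() {
  mk <- function(strain) tibble::tibble(
    gene_id = sprintf("%s_g%02d", strain, 1:11),
    contig = "c1", start = (1:11) * 1000L, end = (1:11) * 1000L + 500L,
    strand = "+", strain = strain)
  ann <- annotate_loci(dplyr::bind_rows(mk("spaa"), mk("spab")))
  # gene k in spaa is homologous to gene k in spab; queries are g06
  clusters <- tibble::tibble(
    protein_id = c(sprintf("spaa_g%02d", 1:11), sprintf("spab_g%02d", 1:11)),
    cluster_label = rep(sprintf("fam%02d", 1:11), 2))
  list(ann = ann, clusters = clusters,
       queries = c("spaa_g06", "spab_g06"))
}

test_that("same-cluster queries with shared neighbour pairs are linked", {
  s <- two_strain_setup()
  snet <- build_synteny_network(s$queries, s$ann, s$clusters, W = 5)
  expect_equal(nrow(snet$edges), 1)
  expect_gte(snet$edges$support, 1)
  # evidence excludes the query cluster itself
  expect_false("fam06" %in% snet$evidence$shared_cluster)
  lin <- infer_lineages(snet)
  expect_equal(length(unique(lin$lineage)), 1)
})

test_that("queries in different sequence clusters are never linked", {
  s <- two_strain_setup()
  cl <- s$clusters
  cl$cluster_label[cl$protein_id == "spab_g06"] <- "other"
  snet <- build_synteny_network(s$queries, s$ann, cl, W = 5)
  expect_equal(nrow(snet$edges), 0)
  lin <- infer_lineages(snet)
  expect_equal(length(unique(lin$lineage)), 2)   # singleton lineages
})

test_that("widening the window never removes synteny edges", {
  set.seed(53)
  u <- simulate_universe(simulation_config(n_species = 4,
                                           filler_genes_per_contig = 20,
                                           seed = 53))
  truth_m <- dplyr::filter(u$truth, startsWith(family, "fam"))
  clusters <- dplyr::transmute(u$truth, protein_id = gene_id,
                               cluster_label = family)
  prev <- NULL
  for (W in c(3, 8, 15)) {
    snet <- build_synteny_network(truth_m$gene_id, u$annotation,
                                  clusters, W = W)
    key <- paste(snet$edges$query_a, snet$edges$query_b)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("heterospecific_only drops within-strain query pairs", {
  mk <- function(strain) tibble::tibble(
    gene_id = sprintf("%s_g%02d", strain, 1:11),
    contig = "c1", start = (1:11) * 1000L, end = (1:11) * 1000L + 500L,
    strand = "+", strain = strain)
  ann <- annotate_loci(mk("spaa"))
  # two tandem queries in one strain, same cluster, shared distinct flanks
  clusters <- tibble::tibble(
    protein_id = sprintf("spaa_g%02d", 1:11),
    cluster_label = c(sprintf("fam%02d", 1:5), "Q", "Q",
                      sprintf("fam%02d", 8:11)))
  clusters$cluster_label[c(3, 9)] <- "shared"
  qs <- c("spaa_g06", "spaa_g07")
  with_intra <- build_synteny_network(qs, ann, clusters, W = 5)
  expect_equal(nrow(with_intra$edges), 1)
  without <- build_synteny_network(qs, ann, clusters, W = 5,
                                   heterospecific_only = TRUE)
  expect_equal(nrow(without$edges), 0)
})

test_that("relaxed-only evidence is tagged and conservative evidence is not", {
  s <- two_strain_setup()
  # conservative clustering knows nothing about the neighbours
  cons <- dplyr::mutate(s$clusters, cluster_label = protein_id)
  cons$cluster_label[cons$protein_id %in% s$queries] <- "fam06"
  snet <- build_synteny_network(s$queries, s$ann, cons,
                                relaxed_clusters = s$clusters, W = 5)
  expect_equal(nrow(snet$edges), 1)
  expect_true(all(snet$edges$relaxed))
  snet2 <- build_synteny_network(s$queries, s$ann, s$clusters,
                                 relaxed_clusters = s$clusters, W = 5)
  expect_false(any(snet2$edges$relaxed))
})

test_that("lineages equal the union-find components of the synteny graph", {
  set.seed(54)
  for (k in 1:10) {
    n <- sample(6:20, 1)
    qs <- sprintf("spaa_g%02d", seq_len(n))
    pairs <- t(utils::combn(qs, 2))
    keep <- stats::runif(nrow(pairs)) < 0.15
    snet <- structure(list(
      queries = qs,
      query_cluster = stats::setNames(rep("famA", n), qs),
      strain = stats::setNames(rep("spaa", n), qs),
      edges = tibble::tibble(query_a = pairs[keep, 1],
                             query_b = pairs[keep, 2],
                             support = 1L, relaxed = FALSE),
      evidence = tibble::tibble(), W = 15), class = "synteny_network")
    lin <- infer_lineages(snet)
    want <- oracle_components(qs, pairs[keep, 1], pairs[keep, 2])
    expect_equal(stats::setNames(lin$lineage, lin$gene_id), want[lin$gene_id])
  }
})

test_that("edge_report sorts evidence by cluster size then closeness", {
  ev <- tibble::tibble(
    neighbour_a = c("x", "y", "z"), offset_a = c(1L, 2L, 3L),
    neighbour_b = c("p", "q", "r"), offset_b = c(1L, 2L, 3L),
    shared_cluster = c("big", "small", "small"),
    cluster_size = c(500L, 2L, 2L), pair_evalue = NA_real_,
    closeness = c(1L, 9L, 4L))
  r <- edge_report(ev)
  expect_equal(r$cluster_size, c(2L, 2L, 500L))
  expect_equal(r$closeness[1:2], c(4L, 9L))
})

test_that("with no rearrangement and no transfer, lineages equal truth families exactly", {
  u <- simulate_universe(simulation_config(
    duplication = 0, loss = 0, hgt = 0, inversion_rate = 0, seed = 55))
  net <- all_vs_all(u$proteins, cutoff_exponent = -12)
  cl <- global_clusters(net, -30)
  truth_m <- dplyr::filter(u$truth, startsWith(family, "fam"))
  snet <- build_synteny_network(truth_m$gene_id, u$annotation, cl,
                                query_clusters = cl, W = 15, net = net)
  lin <- infer_lineages(snet)
  sc <- score_recovery(lin, dplyr::transmute(truth_m, gene_id,
                                             label = family))
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$n_exact, sc$n_truth_groups)
})

test_that("synteny exports carry edge attributes", {
  s <- two_strain_setup()
  snet <- build_synteny_network(s$queries, s$ann, s$clusters, W = 5)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_synteny_graphml(snet, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_true(all(c("support", "min_closeness", "min_cluster_size") %in%
                    igraph::edge_attr_names(g)))
})
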