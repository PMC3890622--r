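test_that("identical seeds reproduce the universe exactly", {
  cfg <- simulation_config(n_species = 4, filler_genes_per_contig = 10,
                           seed = 71)
  u1 <- simulate_universe(cfg)
  u2 <- simulate_universe(cfg)
  expect_identical(u1$proteins, u2$proteins)
  expect_identical(u1$annotation, u2$annotation)
  expect_identical(u1$truth, u2$truth)
  expect_identical(u1$events, u2$events)
  u3 <- simulate_universe(simulation_config(n_species = 4,
                                            filler_genes_per_contig = 10,
                                            seed = 72))
  expect_false(identical(u1$proteins$sequence, u3$proteins$sequence))
})

test_that("the null model emits the root genome unchanged in every species", {
  u <- simulate_universe(simulation_config(
    n_species = 4, filler_genes_per_contig = 8,
    duplication = 0, loss = 0, hgt = 0, inversion_rate = 0,
    substitution = 0, seed = 73))
  by_strain <- split(u$proteins, u$proteins$strain)
  ref <- by_strain[[1]]
  for (s in by_strain[-1]) {
    expect_equal(sub("^[a-z0-9]+_", "", s$id), sub("^[a-z0-9]+_", "", ref$id))
    expect_equal(s$sequence, ref$sequence)
  }
  # each family is one lineage spanning all species
  fam_span <- u$truth |>
    dplyr::group_by(family) |>
    dplyr::summarise(n_lineages = dplyr::n_distinct(lineage),
                     n_species = dplyr::n_distinct(strain))
  expect_true(all(fam_span$n_lineages == 1))
  expect_true(all(fam_span$n_species == 4))
})

test_that("WGD with full retention and no losses doubles every gene", {
  u <- simulate_universe(simulation_config(
    n_species = 2, species_tree = "(sp01:1,sp02:1);",
    filler_genes_per_contig = 6, duplication = 0, loss = 0, hgt = 0,
    inversion_rate = 0, substitution = 0,
    wgd_branches = "sp01", wgd_retention = 1, seed = 74))
  counts <- u$truth |>
    dplyr::count(strain, family)
  expect_true(all(counts$n[counts$strain == "sp01"] == 2))
  expect_true(all(counts$n[counts$strain == "sp02"] == 1))
  # retained duplicates are logged and inherit the parent lineage
  expect_true(all(u$events$type == "wgd"))
  wgd_rows <- dplyr::filter(u$truth, origin == "wgd")
  expect_gt(nrow(wgd_rows), 0)
})

test_that("a WGD branch absent from the tree is a configuration error", {
  cfg <- simulation_config(n_species = 3, wgd_branches = "spXX", seed = 75)
  expect_error(simulate_universe(cfg), "wgd_branches")
})

test_that("expected copy number per family matches the per-branch generative law", {
  # with loss 0 and per-gene duplication probability p per branch, the
  # expected number of extant copies per tip is prod over its root
  # path of (1 + p * t_branch)
  cfg <- simulation_config(
    n_species = 2, species_tree = "(sp01:1,sp02:1);",
    n_families = 1, filler_genes_per_contig = 4,
    duplication = 0.4, loss = 0, hgt = 0, inversion_rate = 0,
    substitution = 0, seed = 76)
  copies <- replicate(150, {
    cfg$seed <- sample.int(1e6, 1)
    u <- simulate_universe(cfg)
    sum(u$truth$family == "fam01" & u$truth$strain == "sp01")
  })
  expect_equal(mean(copies), 1 + 0.4, tolerance = 0.12)
})

test_that("every gene's lineage traces to a root copy or an HGT insertion", {
  u <- simulate_universe(simulation_config(
    n_species = 6, filler_genes_per_contig = 15,
    duplication = 0.1, loss = 0.05, hgt = 1.5, inversion_rate = 0.5,
    seed = 77))
  hgt_births <- u$events$uid[u$events$type == "hgt"]
  root_uids <- sub("^[a-z0-9]+_", "", u$truth$gene_id[u$truth$origin == "root"])
  valid <- u$truth$lineage %in% c(root_uids, hgt_births)
  expect_true(all(valid))
  # HGT recipients carry the donor family but found a new lineage
  hgt_rows <- dplyr::filter(u$truth, origin == "hgt")
  if (nrow(hgt_rows) > 0) {
    expect_true(all(hgt_rows$lineage %in% hgt_births))
  }
  # duplication copies inherit their parent's lineage
  dup_rows <- dplyr::filter(u$truth, origin == "duplication")
  if (nrow(dup_rows) > 0) {
    expect_false(any(dup_rows$lineage %in% u$events$uid[u$events$type == "duplication"]))
  }
})

test_that("emitted files are valid pipeline inputs", {
  u <- simulate_universe(simulation_config(n_species = 3,
                                           filler_genes_per_contig = 6,
                                           seed = 78))
  d <- withr::local_tempdir()
  write_universe(u, d)
  fa <- read_fasta(file.path(d, "sp01.faa"))
  expect_gt(nrow(fa), 0)
  ann <- read_annotation(file.path(d, "sp01.tsv"))
  expect_equal(sort(ann$gene_id), sort(fa$id))
  tr <- read_newick(file.path(d, "species_tree.nwk"))
  expect_equal(sort(tr$tip.label), c("sp01", "sp02", "sp03"))
})

test_that("score_recovery metrics are exact on hand-checkable partitions", {
  ids <- sprintf("g%02d", 1:10)
  truth <- tibble::tibble(gene_id = ids, label = "L1")
  perfect <- tibble::tibble(gene_id = ids, label = "A")
  sc <- score_recovery(perfect, truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$ari, 1)
  expect_equal(sc$n_exact, 1L)
  # all singletons against one 10-gene truth group
  singletons <- tibble::tibble(gene_id = ids, label = ids)
  sc <- score_recovery(singletons, truth)
  expect_equal(sc$precision, 1)   # no inferred pairs: 1 by convention
  expect_equal(sc$recall, 0)
  expect_equal(sc$f1, 0)
  expect_equal(sc$ari, 0)         # contingency formula: no agreement above chance
})

test_that("adjusted Rand index matches the independent contingency oracle", {
  skip_if_not_installed("mclust")
  set.seed(79)
  for (k in 1:20) {
    n <- sample(10:50, 1)
    ids <- sprintf("g%03d", seq_len(n))
    a <- sample(letters[1:4], n, replace = TRUE)
    b <- sample(letters[1:5], n, replace = TRUE)
    sc <- score_recovery(tibble::tibble(gene_id = ids, label = a),
                         tibble::tibble(gene_id = ids, label = b))
    expect_equal(sc$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("genes present in only one labelling are counted as unmatched singletons", {
  truth <- tibble::tibble(gene_id = sprintf("g%02d", 1:6), label = "L1")
  inferred <- tibble::tibble(gene_id = sprintf("g%02d", 1:4), label = "A")
  sc <- score_recovery(inferred, truth)
  expect_equal(sc$n_unmatched, 2L)
  expect_equal(sc$recall, choose(4, 2) / choose(6, 2))
})
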