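chain_net <- function(...) {
  ids <- c(...)
  similarity_network(tibble::tibble(
    from = ids[-length(ids)], to = ids[-1],
    evalue = rep(1e-40, length(ids) - 1)), nodes = ids)
}

test_that("constrain keeps nodes and filters edges by threshold", {
  net <- similarity_network(
    tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                   evalue = c(1e-35, 1e-18)))
  expect_equal(nrow(constrain(net, -30)$edges), 1)
  expect_equal(constrain(net, -30)$edges$from, "A")
  expect_equal(nrow(constrain(net, -15)$edges), 2)
  expect_equal(nrow(constrain(net, -40)$edges), 0)
  expect_equal(constrain(net, -40)$nodes, c("A", "B", "C"))
})

test_that("duplicate and reversed edges collapse to the most significant E-value", {
  net <- similarity_network(tibble::tibble(
    from = c("A", "B", "A"), to = c("B", "A", "A"),
    evalue = c(1e-12, 1e-40, 1e-99)))
  expect_equal(nrow(net$edges), 1)       # self-loop dropped, pair deduplicated
  expect_equal(net$edges$evalue, 1e-40)
})

test_that("traverse returns the seed's component in breadth-first lexicographic order", {
  net <- chain_net("A", "B", "C")
  expect_equal(traverse(net, "A"), c("A", "B", "C"))
  expect_error(traverse(net, "Z"), "unknown seed")
  iso <- similarity_network(tibble::tibble(from = character(0),
                                           to = character(0),
                                           evalue = double(0)),
                            nodes = c("A", "B"))
  expect_equal(traverse(iso, "A"), "A")
  # star: neighbours of the hub are visited in lexicographic order
  star <- similarity_network(tibble::tibble(
    from = rep("M", 3), to = c("Z", "A", "Q"), evalue = rep(1e-40, 3)))
  expect_equal(traverse(star, "M"), c("M", "A", "Q", "Z"))
})

test_that("global_clusters labels components by smallest member", {
  tri <- function(a, b, c) tibble::tibble(from = c(a, b, a), to = c(b, c, c),
                                          evalue = rep(1e-40, 3))
  net <- similarity_network(dplyr::bind_rows(tri("A", "B", "C"),
                                             tri("X", "Y", "Z")))
  cl <- global_clusters(net, -30)
  expect_equal(sort(unique(cl$cluster_label)), c("A", "X"))
  expect_equal(unique(cl$cluster_size), 3L)
  expect_equal(nrow(cl), 6)
})

test_that("traversal and clustering agree with the union-find oracle on random graphs", {
  set.seed(21)
  for (k in 1:20) {
    net <- random_network(sample(20:80, 1), stats::runif(1, 0.02, 0.2))
    cl <- global_clusters(net, -5)
    want <- oracle_components(net$nodes, net$edges$from, net$edges$to)
    expect_equal(stats::setNames(cl$cluster_label, cl$protein_id), want)
    seed <- sample(net$nodes, 1)
    expect_setequal(traverse(net, seed),
                    names(want)[want == want[[seed]]])
  }
})

test_that("sweep profiles are monotone, pure, and constant for a single node", {
  one <- similarity_network(tibble::tibble(from = character(0),
                                           to = character(0),
                                           evalue = double(0)),
                            nodes = "A")
  prof <- sweep_thresholds(one, "A")
  expect_true(all(prof$retrieved == 1))
  set.seed(22)
  for (k in 1:5) {
    net <- random_network(40, 0.05)
    seed <- sample(net$nodes, 1)
    p1 <- sweep_thresholds(net, seed, -30:-12)
    expect_true(all(diff(p1$retrieved) >= 0))
    expect_identical(p1, sweep_thresholds(net, seed, -30:-12))
  }
})

test_that("relaxing the threshold only merges clusters (partition refinement)", {
  set.seed(23)
  for (k in 1:5) {
    net <- random_network(50, 0.08)
    fine <- global_clusters(net, -30)
    coarse <- global_clusters(net, -15)
    merged <- dplyr::inner_join(fine, coarse, by = "protein_id",
                                suffix = c("_f", "_c"))
    # every fine cluster maps into exactly one coarse cluster
    viol <- merged |>
      dplyr::group_by(cluster_label_f) |>
      dplyr::summarise(n = dplyr::n_distinct(cluster_label_c))
    expect_true(all(viol$n == 1))
  }
})

test_that("detect_ranges reproduces the plateau structure of a sweep profile", {
  # profile shaped like the published sweep: plateaus of 68, 393 and
  # 402 sequences over -30..-21, -20..-18 and -17..-15
  prof <- tibble::tibble(
    exponent = -30:-15,
    retrieved = c(rep(68L, 10), rep(393L, 3), rep(402L, 3)))
  r <- detect_ranges(prof)
  expect_equal(r$exponent_lo, c(-30L, -20L, -17L))
  expect_equal(r$exponent_hi, c(-21L, -18L, -15L))
  expect_equal(r$count, c(68L, 393L, 402L))

  flat <- tibble::tibble(exponent = -30:-12, retrieved = 5L)
  expect_equal(nrow(detect_ranges(flat)), 1)

  inc <- tibble::tibble(exponent = -20:-15, retrieved = 1:6)
  expect_equal(nrow(detect_ranges(inc)), 6)
  # a tolerance absorbs small drift into one range
  expect_equal(nrow(detect_ranges(inc, tolerance = 1)), 1)
})

test_that("ranges concatenate to cover the profile exactly", {
  set.seed(24)
  for (k in 1:10) {
    prof <- tibble::tibble(
      exponent = -30:-12,
      retrieved = cumsum(sample(0:3, 19, replace = TRUE)))
    r <- detect_ranges(prof)
    covered <- unlist(Map(seq, r$exponent_lo, r$exponent_hi))
    expect_equal(sort(covered), prof$exponent)
  }
})

test_that("network exports are readable and preserve structure", {
  net <- chain_net("A", "B", "C")
  g_file <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, g_file)
  g <- igraph::read_graph(g_file, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  s_file <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, s_file)
  expect_equal(length(readLines(s_file)), 2)
})

test_that("tidy and glance summarise a similarity network", {
  net <- chain_net("A", "B", "C")
  expect_equal(nrow(tidy(net)), 2)
  g <- glance(net)
  expect_equal(g$n_nodes, 3L)
  expect_equal(g$n_components, 1L)
})
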