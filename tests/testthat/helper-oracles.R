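# Independent oracles used across the suite. Each one re-derives the
# quantity it checks from first principles, sharing no code with the
# implementation under test.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

blosum <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

random_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Full-matrix three-state Gotoh with transitions between all states.
# Gap of length L costs go + L * ge, matching the package convention.
oracle_align_score <- function(a, b, mat, go, ge, local = TRUE) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  NI <- -1e18
  M <- matrix(NI, m + 1, n + 1)
  X <- matrix(NI, m + 1, n + 1) # gap in b (consumes a)
  Y <- matrix(NI, m + 1, n + 1) # gap in a (consumes b)
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(m + 1)) X[i, 1] <- -(go + ge * (i - 1))
    for (j in 2:(n + 1)) Y[1, j] <- -(go + ge * (j - 1))
  }
  best <- 0
  for (i in 1:m) {
    for (j in 1:n) {
      s <- mat[A[i], B[j]]
      d <- max(M[i, j], X[i, j], Y[i, j]) + s
      if (local) d <- max(d, s)
      M[i + 1, j + 1] <- d
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge,
                             X[i + 1, j] - go - ge)
      if (local) best <- max(best, M[i + 1, j + 1])
    }
  }
  if (local) max(best, 0) else max(M[m + 1, n + 1], X[m + 1, n + 1],
                                   Y[m + 1, n + 1])
}

# union-find connected components; labels = smallest member
oracle_components <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (length(from) > 0) {
    for (k in seq_along(from)) {
      ra <- find(from[k])
      rb <- find(to[k])
      if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
    }
  }
  labels <- vapply(nodes, find, character(1))
  # canonicalise to smallest member per component
  split_members <- split(nodes, labels)
  canon <- vapply(split_members, min, character(1))
  stats::setNames(canon[labels], nodes)
}

# random similarity network: n nodes, edge prob p, log10 E-values
# uniform on [-45, -5]
random_network <- function(n, p) {
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- tibble::tibble(
    from = pairs[keep, 1], to = pairs[keep, 2],
    log10_evalue = stats::runif(sum(keep), -45, -5)
  )
  similarity_network(edges, nodes = ids)
}

# brute-force shared neighbour pair enumeration over two windows:
# every (i, j) cell of the full cross product is tested individually
oracle_shared_pairs <- function(win_a, win_b, clusters, exclude = NULL) {
  lab <- stats::setNames(clusters$cluster_label, clusters$protein_id)
  grid <- expand.grid(i = seq_len(nrow(win_a)), j = seq_len(nrow(win_b)))
  na <- win_a$neighbour[grid$i]
  nb <- win_b$neighbour[grid$j]
  ca <- unname(lab[na])
  cb <- unname(lab[nb])
  keep <- na != nb & !is.na(ca) & !is.na(cb) & ca == cb
  if (!is.null(exclude)) keep <- keep & !ca %in% exclude
  oa <- win_a$offset[grid$i][keep]
  ob <- win_b$offset[grid$j][keep]
  tibble::tibble(
    neighbour_a = na[keep], offset_a = oa,
    neighbour_b = nb[keep], offset_b = ob,
    shared_cluster = ca[keep],
    closeness = pmax(abs(oa), abs(ob)))
}

# random additive distance matrix from a random tree, plus the tree
random_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

tiny_annotation <- function(genes_per_contig, contigs = 1, strain = "spaa") {
  rows <- list()
  for (c_i in seq_len(contigs)) {
    n <- genes_per_contig
    rows[[c_i]] <- tibble::tibble(
      gene_id = sprintf("%s_c%dg%02d", strain, c_i, seq_len(n)),
      contig = paste0("ctg", c_i),
      start = seq_len(n) * 1000L,
      end = seq_len(n) * 1000L + 500L,
      strand = rep(c("+", "-"), length.out = n),
      strain = strain
    )
  }
  annotate_loci(dplyr::bind_rows(rows))
}
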