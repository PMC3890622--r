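#' Pairwise distances from a multiple sequence alignment
#'
#' For each sequence pair, columns with a gap in either sequence are
#' skipped; `p` is the fraction of mismatches among compared columns
#' and the Poisson-corrected distance is `-ln(1 - p)`, capped at
#' `max_distance` when `p` approaches or reaches 1.
#'
#' @param msa Aligned records: a tibble with `id` and `sequence`
#'   columns (equal-length gapped strings, `-` for gaps) or a named
#'   character vector.
#' @param model `"poisson"` (default) or `"p"`.
#' @param max_distance Cap applied when the Poisson correction diverges
#'   (default 10).
#' @return A symmetric numeric matrix with zero diagonal, taxa as
#'   dimnames.
#' @export
distance_from_msa <- function(msa, model = c("poisson", "p"),
                              max_distance = 10) {
  model <- match.arg(model)
  if (is.data.frame(msa)) {
    seqs <- setNames(msa$sequence, msa$id)
  } else {
    seqs <- msa
  }
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1) {
    abort("aligned sequences must all have the same length")
  }
  chars <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  gap <- chars == "-"
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        abort(sprintf("no comparable columns between %s and %s",
                      names(seqs)[i], names(seqs)[j]))
      }
      p <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
      d <- if (model == "p") p else if (p >= 1) max_distance
           else min(-log(1 - p), max_distance)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Read an aligned FASTA file (gapped sequences allowed)
#'
#' Unlike [read_fasta()], gap characters (`-`) are accepted; use this
#' for multiple sequence alignments consumed by [distance_from_msa()].
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of equal-length gapped sequences.
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (length(unique(nchar(seqs))) != 1) {
    abort("aligned FASTA has sequences of unequal length")
  }
  seqs
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; negative branch lengths (which NJ can
#' produce on non-additive matrices) are clamped to zero and the total
#' clamped deficit recorded in the `clamped_deficit` attribute.
#'
#' @param D Symmetric distance matrix with taxa dimnames (at least 3).
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) >= 3, identical(rownames(D), colnames(D)))
  tree <- ape::nj(as.dist(D))
  neg <- tree$edge.length < 0
  deficit <- -sum(tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  attr(tree, "clamped_deficit") <- deficit
  tree
}

#' Root a tree on the branch subtending an outgroup leaf
#'
#' @param tree A `phylo` tree.
#' @param outgroup Leaf label to root at.
#' @return The rooted `phylo` tree; the leaf set is unchanged.
#' @export
reroot_at <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    abort(paste0("unknown leaf: ", outgroup))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D Symmetric distance matrix with taxa dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  n <- nrow(D)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(rownames(D)[i], width = -10),
                      paste(formatC(D[i, ], format = "f", digits = 6),
                            collapse = "  "))
             }, character(1)))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path Path to the file.
#' @return A symmetric numeric matrix with taxa dimnames.
#' @export
read_phylip_dist <- function(path) {
  lines <- readr::read_lines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  taxa <- vapply(parts, `[[`, character(1), 1)
  D <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  dimnames(D) <- list(taxa, taxa)
  D
}

#' Write a tree in newick format
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
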