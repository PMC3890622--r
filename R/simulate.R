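HYDROPHOBIC_AA <- c("I", "L", "V", "F", "M", "A")
HYDROPHILIC_AA <- c("D", "E", "K", "R", "S", "T", "N", "Q", "G", "P", "H")

#' Configure a genome-evolution simulation
#'
#' The simulator evolves an ancestral genome down a species tree under
#' gene duplication, loss, horizontal transfer, optional whole-genome
#' duplication, chromosomal inversions and residue substitution, and
#' emits per-species proteomes and annotations together with
#' ground-truth family and lineage labels. Defaults describe a gentle
#' regime: 8 species, 4 transporter-like marker families embedded among
#' filler genes, low rearrangement, moderate sequence divergence.
#'
#' All rates are per unit branch length (the generated species tree is
#' scaled to height 1). `duplication` and `loss` are per-gene
#' probabilities scaled by branch length; `hgt` and `inversion_rate`
#' are Poisson intensities per branch.
#'
#' @param n_species Number of extant species (default 8).
#' @param species_tree Optional newick string; otherwise a random
#'   coalescent tree scaled to height 1 is generated from the seed.
#' @param n_families Number of marker gene families (default 4).
#' @param n_contigs Contigs in the ancestral genome (default 2).
#' @param filler_genes_per_contig Filler genes per contig (default 40).
#' @param marker_tms,marker_tms_len,marker_loop_len,marker_tail
#'   Architecture of marker proteins: number of hydrophobic stretches,
#'   their length, loop length, and terminal tail length. Defaults
#'   (14, 21, 12, 25) give 500-residue 14-segment membrane-protein-like
#'   sequences.
#' @param filler_len Filler protein length (default 150).
#' @param duplication Per-gene duplication probability per unit branch
#'   (default 0.01).
#' @param loss Per-gene loss probability per unit branch (default 0.01).
#' @param tandem_prob Probability a duplicate inserts adjacent to its
#'   parent rather than relocating (default 0.5).
#' @param hgt Horizontal-transfer intensity per unit branch
#'   (default 0.05).
#' @param hgt_with_context Transfer a flanking block (the donor gene
#'   plus one neighbour each side) instead of the gene alone
#'   (default `FALSE`).
#' @param wgd_branches Branches carrying a whole-genome duplication,
#'   named by the child node (tip label, or `"nodeN"` for internal
#'   node N). Default none.
#' @param wgd_retention Probability each WGD duplicate is retained
#'   (default 0.5).
#' @param inversion_rate Inversion intensity per unit branch
#'   (default 0.2).
#' @param inversion_mean_len Mean inversion tract length in genes
#'   (default 4).
#' @param subtelomeric_relocation Extra relocation probability for genes
#'   within 3 genes of a contig end (default 0, off).
#' @param substitution Expected residue replacements per site per unit
#'   branch length (default 0.3).
#' @param seed Integer RNG seed; the same seed and configuration
#'   reproduce the universe byte for byte.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 8, species_tree = NULL,
                              n_families = 4, n_contigs = 2,
                              filler_genes_per_contig = 40,
                              marker_tms = 14, marker_tms_len = 21,
                              marker_loop_len = 12, marker_tail = 25,
                              filler_len = 150,
                              duplication = 0.01, loss = 0.01,
                              tandem_prob = 0.5,
                              hgt = 0.05, hgt_with_context = FALSE,
                              wgd_branches = character(0),
                              wgd_retention = 0.5,
                              inversion_rate = 0.2,
                              inversion_mean_len = 4,
                              subtelomeric_relocation = 0,
                              substitution = 0.3, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_species >= 2, n_families >= 1, n_contigs >= 1,
            duplication >= 0, loss >= 0, hgt >= 0,
            inversion_rate >= 0, substitution >= 0,
            wgd_retention >= 0, wgd_retention <= 1,
            tandem_prob >= 0, tandem_prob <= 1)
  structure(cfg, class = "simulation_config")
}

random_protein <- function(len) {
  paste(sample(names(AA_BACKGROUND), len, replace = TRUE,
               prob = AA_BACKGROUND), collapse = "")
}

marker_protein <- function(cfg) {
  tail_seq <- function() paste(sample(names(AA_BACKGROUND), cfg$marker_tail,
                                      replace = TRUE, prob = AA_BACKGROUND),
                               collapse = "")
  stretch <- function() paste(sample(HYDROPHOBIC_AA, cfg$marker_tms_len,
                                     replace = TRUE), collapse = "")
  loop <- function() paste(sample(HYDROPHILIC_AA, cfg$marker_loop_len,
                                  replace = TRUE), collapse = "")
  parts <- character(0)
  for (k in seq_len(cfg$marker_tms)) {
    parts <- c(parts, stretch())
    if (k < cfg$marker_tms) parts <- c(parts, loop())
  }
  paste0(tail_seq(), paste(parts, collapse = ""), tail_seq())
}

mutate_sequence <- function(seq, p) {
  if (p <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, p)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- sample(names(AA_BACKGROUND), k, replace = TRUE,
                    prob = AA_BACKGROUND)
  paste(ch, collapse = "")
}

#' Simulate a genome universe with ground truth
#'
#' Builds the ancestral genome (one root copy per marker family
#' interleaved with filler genes, each filler its own single-copy
#' family), then walks the species tree applying, per branch:
#' substitutions, losses, duplications (tandem or relocating), HGT
#' insertions copied from a contemporaneous donor genome in another
#' clade, whole-genome duplication where configured, and inversions.
#' Every extant gene carries a family label (its root family) and a
#' lineage label: the ancestral root copy — or HGT insertion — its
#' history traces back to. Duplication and WGD copies inherit their
#' parent's lineage (paralog pairs retained in conserved neighbourhood
#' context belong to one lineage); a horizontal transfer founds a new
#' lineage in the recipient clade.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_universe`: tibbles `proteins`
#'   (id, strain, sequence, length), `annotation` (gene_id, strain,
#'   contig, start, end, strand, ordinal), `truth` (gene_id, strain,
#'   family, lineage, origin), `events`, plus the species `tree` and
#'   the `config`.
#' @export
simulate_universe <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)

  strains <- sprintf("sp%02d", seq_len(cfg$n_species))
  if (is.null(cfg$species_tree)) {
    tree <- ape::rcoal(cfg$n_species, tip.label = strains)
  } else {
    tree <- ape::read.tree(text = cfg$species_tree)
    if (is.null(tree$tip.label) || ape::Ntip(tree) != cfg$n_species) {
      abort("species_tree tip count does not match n_species")
    }
    strains <- tree$tip.label
  }
  # scale to height 1 so rates are per fraction of total divergence time
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length / max(depths)

  ntip <- ape::Ntip(tree)
  node_name <- function(v) if (v <= ntip) tree$tip.label[v] else paste0("node", v)
  all_branch_names <- vapply(tree$edge[, 2], node_name, character(1))
  bad_wgd <- setdiff(cfg$wgd_branches, all_branch_names)
  if (length(bad_wgd) > 0) {
    abort(paste0("wgd_branches not present in the species tree: ",
                 paste(bad_wgd, collapse = ", ")))
  }

  counter <- 0L
  new_uid <- function() {
    counter <<- counter + 1L
    sprintf("g%06d", counter)
  }
  registry <- list()   # uid -> list(family, lineage, origin, parent)
  events <- list()
  log_event <- function(branch, type, uid, parent = NA_character_,
                        detail = NA_character_) {
    events[[length(events) + 1]] <<- tibble(
      branch = branch, type = type, uid = uid, parent = parent,
      detail = detail)
  }

  # ---- root genome ----------------------------------------------------
  contigs <- list()
  strand <- character(0)
  seqs <- list()
  filler_ids <- character(0)
  for (c_i in seq_len(cfg$n_contigs)) {
    uids <- character(cfg$filler_genes_per_contig)
    for (k in seq_len(cfg$filler_genes_per_contig)) {
      uid <- new_uid()
      uids[k] <- uid
      registry[[uid]] <- list(family = paste0("flr_", uid), lineage = uid,
                              origin = "root", parent = NA_character_)
      seqs[[uid]] <- random_protein(cfg$filler_len)
      strand[uid] <- sample(c("+", "-"), 1)
    }
    contigs[[paste0("ctg", c_i)]] <- uids
    filler_ids <- c(filler_ids, uids)
  }
  for (f in seq_len(cfg$n_families)) {
    uid <- new_uid()
    registry[[uid]] <- list(family = sprintf("fam%02d", f), lineage = uid,
                            origin = "root", parent = NA_character_)
    seqs[[uid]] <- marker_protein(cfg)
    strand[uid] <- sample(c("+", "-"), 1)
    ci <- sample(length(contigs), 1)
    pos <- sample(length(contigs[[ci]]) + 1, 1)
    contigs[[ci]] <- append(contigs[[ci]], uid, after = pos - 1)
  }
  root_genome <- list(contigs = contigs, strand = strand, seqs = seqs)

  # ---- evolution along branches --------------------------------------
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  root <- ntip + 1L
  genomes <- list()
  genomes[[root]] <- root_genome
  ancestors <- list()
  ancestors[[root]] <- root
  snapshots <- integer(0)   # nodes whose genomes may donate HGT copies

  genome_genes <- function(g) unlist(g$contigs, use.names = FALSE)

  insert_gene <- function(g, uid, near = NULL) {
    if (!is.null(near)) {
      for (ci in seq_along(g$contigs)) {
        at <- match(near, g$contigs[[ci]])
        if (!is.na(at)) {
          g$contigs[[ci]] <- append(g$contigs[[ci]], uid, after = at)
          return(g)
        }
      }
    }
    ci <- sample(length(g$contigs), 1)
    pos <- sample(length(g$contigs[[ci]]) + 1, 1)
    g$contigs[[ci]] <- append(g$contigs[[ci]], uid, after = pos - 1)
    g
  }

  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    t_len <- tree$edge.length[e]
    bname <- node_name(child)
    g <- genomes[[parent]]
    ancestors[[child]] <- c(ancestors[[parent]], child)

    # substitutions
    p_sub <- 1 - exp(-cfg$substitution * t_len)
    for (uid in genome_genes(g)) {
      g$seqs[[uid]] <- mutate_sequence(g$seqs[[uid]], p_sub)
    }

    # losses
    p_loss <- 1 - exp(-cfg$loss * t_len)
    if (p_loss > 0) {
      for (ci in seq_along(g$contigs)) {
        uids <- g$contigs[[ci]]
        lost <- uids[runif(length(uids)) < p_loss]
        if (length(lost) > 0) {
          g$contigs[[ci]] <- setdiff(uids, lost)
          for (u in lost) log_event(bname, "loss", u)
        }
      }
    }

    # duplications
    p_dup <- cfg$duplication * t_len
    if (p_dup > 0) {
      for (uid in genome_genes(g)) {
        if (runif(1) >= p_dup) next
        nu <- new_uid()
        registry[[nu]] <- list(family = registry[[uid]]$family,
                               lineage = registry[[uid]]$lineage,
                               origin = "duplication", parent = uid)
        g$seqs[[nu]] <- g$seqs[[uid]]
        g$strand[nu] <- g$strand[[uid]]
        tandem <- runif(1) < cfg$tandem_prob
        g <- insert_gene(g, nu, near = if (tandem) uid else NULL)
        log_event(bname, "duplication", nu, uid,
                  if (tandem) "tandem" else "relocated")
      }
    }

    # horizontal transfers from a contemporaneous donor clade
    n_hgt <- if (cfg$hgt > 0) rpois(1, cfg$hgt * t_len) else 0L
    if (n_hgt > 0) {
      donors <- setdiff(snapshots, ancestors[[child]])
      for (k in seq_len(n_hgt)) {
        if (length(donors) == 0) break
        dg <- genomes[[if (length(donors) == 1) donors else sample(donors, 1)]]
        pool <- genome_genes(dg)
        if (length(pool) == 0) next
        src <- if (length(pool) == 1) pool else sample(pool, 1)
        block <- src
        if (cfg$hgt_with_context) {
          for (ci in seq_along(dg$contigs)) {
            at <- match(src, dg$contigs[[ci]])
            if (!is.na(at)) {
              lo <- max(1, at - 1)
              hi <- min(length(dg$contigs[[ci]]), at + 1)
              block <- dg$contigs[[ci]][lo:hi]
              break
            }
          }
        }
        prev <- NULL
        for (src_u in block) {
          nu <- new_uid()
          registry[[nu]] <- list(family = registry[[src_u]]$family,
                                 lineage = nu, origin = "hgt",
                                 parent = src_u)
          g$seqs[[nu]] <- dg$seqs[[src_u]]
          g$strand[nu] <- dg$strand[[src_u]]
          g <- insert_gene(g, nu, near = prev)
          prev <- nu
          log_event(bname, "hgt", nu, src_u)
        }
      }
    }

    # whole-genome duplication
    if (bname %in% cfg$wgd_branches) {
      new_contigs <- list()
      for (ci in seq_along(g$contigs)) {
        dup_uids <- character(0)
        for (uid in g$contigs[[ci]]) {
          if (runif(1) > cfg$wgd_retention) next
          nu <- new_uid()
          registry[[nu]] <- list(family = registry[[uid]]$family,
                                 lineage = registry[[uid]]$lineage,
                                 origin = "wgd", parent = uid)
          g$seqs[[nu]] <- g$seqs[[uid]]
          g$strand[nu] <- g$strand[[uid]]
          dup_uids <- c(dup_uids, nu)
          log_event(bname, "wgd", nu, uid)
        }
        if (length(dup_uids) > 0) {
          new_contigs[[paste0(names(g$contigs)[ci], "w")]] <- dup_uids
        }
      }
      g$contigs <- c(g$contigs, new_contigs)
    }

    # inversions
    n_inv <- if (cfg$inversion_rate > 0) rpois(1, cfg$inversion_rate * t_len) else 0L
    for (k in seq_len(n_inv)) {
      sizes <- lengths(g$contigs)
      if (all(sizes < 2)) break
      ci <- sample(length(g$contigs), 1, prob = sizes / sum(sizes))
      len_c <- sizes[ci]
      if (len_c < 2) next
      tract <- min(len_c, 1 + stats::rgeom(1, 1 / cfg$inversion_mean_len))
      start <- sample(len_c - tract + 1, 1)
      idx <- start:(start + tract - 1)
      seg <- rev(g$contigs[[ci]][idx])
      g$contigs[[ci]][idx] <- seg
      g$strand[seg] <- ifelse(g$strand[seg] == "+", "-", "+")
      log_event(bname, "inversion", seg[1], detail = sprintf("len=%d", tract))
    }

    genomes[[child]] <- g
    snapshots <- c(snapshots, child)
  }

  # ---- emit extant species -------------------------------------------
  prot_rows <- list()
  ann_rows <- list()
  truth_rows <- list()
  for (v in seq_len(ntip)) {
    sp <- tree$tip.label[v]
    g <- genomes[[v]]
    for (ci in seq_along(g$contigs)) {
      uids <- g$contigs[[ci]]
      if (length(uids) == 0) next
      lens <- vapply(uids, function(u) nchar(g$seqs[[u]]), integer(1))
      starts <- 1L + (seq_along(uids) - 1L) * 2000L
      ids <- paste0(sp, "_", uids)
      prot_rows[[length(prot_rows) + 1]] <- tibble(
        id = ids, strain = sp,
        sequence = unname(vapply(uids, function(u) g$seqs[[u]],
                                 character(1))),
        length = unname(lens))
      ann_rows[[length(ann_rows) + 1]] <- tibble(
        gene_id = ids, strain = sp, contig = names(g$contigs)[ci],
        start = starts, end = starts + unname(lens) * 3L + 2L,
        strand = unname(g$strand[uids]),
        ordinal = seq_along(uids) - 1L)
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        gene_id = ids, strain = sp,
        family = vapply(uids, function(u) registry[[u]]$family, character(1)),
        lineage = vapply(uids, function(u) registry[[u]]$lineage, character(1)),
        origin = vapply(uids, function(u) registry[[u]]$origin, character(1)))
    }
  }

  structure(
    list(proteins = bind_rows(prot_rows),
         annotation = bind_rows(ann_rows),
         truth = bind_rows(truth_rows),
         events = if (length(events) > 0) bind_rows(events) else
           tibble(branch = character(0), type = character(0),
                  uid = character(0), parent = character(0),
                  detail = character(0)),
         tree = tree, config = cfg),
    class = "simulated_universe"
  )
}

#' @export
print.simulated_universe <- function(x, ...) {
  cat(sprintf("<simulated_universe> %d species, %d genes (%d marker-family), %d events\n",
              length(unique(x$proteins$strain)), nrow(x$proteins),
              sum(startsWith(x$truth$family, "fam")), nrow(x$events)))
  invisible(x)
}

#' @rdname simulate_universe
#' @param x A `simulated_universe`.
#' @param ... Unused.
#' @export
glance.simulated_universe <- function(x, ...) {
  tibble(n_species = length(unique(x$proteins$strain)),
         n_genes = nrow(x$proteins),
         n_marker_genes = sum(startsWith(x$truth$family, "fam")),
         n_families = length(unique(x$truth$family)),
         n_lineages = length(unique(x$truth$lineage)),
         n_events = nrow(x$events))
}

#' Write a simulated universe to disk in pipeline input formats
#'
#' One proteome FASTA and one annotation TSV per species, plus the
#' truth table, event log, species tree (newick) and the configuration
#' (YAML).
#'
#' @param universe A [simulate_universe()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in unique(universe$proteins$strain)) {
    write_fasta(filter(universe$proteins, .data$strain == sp),
                file.path(dir, paste0(sp, ".faa")))
    readr::write_tsv(filter(universe$annotation, .data$strain == sp),
                     file.path(dir, paste0(sp, ".tsv")))
  }
  readr::write_tsv(universe$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(universe$events, file.path(dir, "events.tsv"))
  ape::write.tree(universe$tree, file.path(dir, "species_tree.nwk"))
  cfg <- universe$config
  cfg$species_tree <- if (is.null(cfg$species_tree)) "" else cfg$species_tree
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

pair_count <- function(n) sum(choose(n, 2))

#' Score recovered clusters or lineages against ground truth
#'
#' Pairwise precision, recall and F1 over co-assigned gene pairs, the
#' adjusted Rand index, and the number of truth groups recovered
#' exactly. Genes present in only one of the two labellings are treated
#' as singletons on the other side and counted in `n_unmatched`.
#'
#' @param inferred Tibble with columns `gene_id` and a label column
#'   (`lineage`, `cluster_label` or `label`).
#' @param truth Tibble with columns `gene_id` and a label column.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `ari`,
#'   `n_exact`, `n_truth_groups`, `n_inferred_groups`, `n_unmatched`.
#' @export
score_recovery <- function(inferred, truth) {
  pick_label <- function(df) {
    col <- intersect(c("lineage", "cluster_label", "family", "label"),
                     names(df))[1]
    idcol <- intersect(c("gene_id", "protein_id", "id"), names(df))[1]
    if (is.na(col) || is.na(idcol)) abort("no label / id column found")
    tibble(gene_id = df[[idcol]], label = df[[col]])
  }
  inf <- pick_label(inferred)
  tru <- pick_label(truth)
  universe <- union(inf$gene_id, tru$gene_id)
  n_unmatched <- length(setdiff(universe, inf$gene_id)) +
    length(setdiff(universe, tru$gene_id))
  # missing genes become singletons labelled by themselves
  fill <- function(df) {
    miss <- setdiff(universe, df$gene_id)
    bind_rows(df, tibble(gene_id = miss, label = paste0(".s_", miss)))
  }
  inf <- fill(inf)
  tru <- fill(tru)
  m <- inner_join(inf, tru, by = "gene_id", suffix = c("_inf", "_tru"))
  tab <- table(m$label_inf, m$label_tru)
  tp <- pair_count(as.vector(tab))
  pairs_inf <- pair_count(rowSums(tab))
  pairs_tru <- pair_count(colSums(tab))
  precision <- if (pairs_inf == 0) 1 else tp / pairs_inf
  recall <- if (pairs_tru == 0) 1 else tp / pairs_tru
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  n <- nrow(m)
  expected <- pairs_inf * pairs_tru / pair_count(n)
  max_index <- (pairs_inf + pairs_tru) / 2
  ari <- if (max_index == expected) 1 else
    (tp - expected) / (max_index - expected)
  sets_inf <- split(m$gene_id, m$label_inf)
  sets_tru <- split(m$gene_id, m$label_tru)
  key <- function(s) paste(sort(s), collapse = "\r")
  n_exact <- sum(vapply(sets_tru, key, character(1)) %in%
                   vapply(sets_inf, key, character(1)))
  tibble(precision = precision, recall = recall, f1 = f1, ari = ari,
         n_exact = n_exact, n_truth_groups = length(sets_tru),
         n_inferred_groups = length(sets_inf), n_unmatched = n_unmatched)
}
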