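#' Assemble a pipeline configuration
#'
#' Collects every numeric constant of the analysis in one place. The
#' defaults are the method's canonical settings: similarity network cut
#' at E-15, neighbour clustering at the conservative E-30 with an E-15
#' relaxed fallback, 15-gene windows, the 490-residue / 14-TMS
#' full-size screen, and needle-default global alignment penalties.
#'
#' @param fasta Character vector of proteome FASTA paths (one per
#'   strain), or `NULL` when `simulate` is given.
#' @param annotations Matching annotation TSV paths.
#' @param simulate Optional list of [simulation_config()] arguments; the
#'   pipeline then generates its own inputs.
#' @param outdir Output directory for all artifacts.
#' @param cutoff_exponent All-vs-all E-value cutoff exponent
#'   (default -15).
#' @param neighbour_exponent Conservative neighbour-clustering exponent
#'   (default -30).
#' @param relaxed_exponent Relaxed fallback exponent (default -15).
#' @param W Neighbourhood window half-width (default 15).
#' @param seeds Protein IDs used as traversal seeds; the union of their
#'   components at `cutoff_exponent` becomes the query set. Empty:
#'   every protein is a query.
#' @param expected_tms,len_cutoff Full-size screen constants
#'   (defaults 14 and 490).
#' @param gap_open,gap_extend,matrix Global-alignment parameters
#'   (defaults 10.0, 0.5, BLOSUM62).
#' @param tree_model Distance model for the tree stage (default
#'   `"poisson"`).
#' @param tree_root Optional outgroup leaf for rooting.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, annotations = NULL,
                            simulate = NULL, outdir = "famsyn_out",
                            cutoff_exponent = -15,
                            neighbour_exponent = -30,
                            relaxed_exponent = -15, W = 15,
                            seeds = character(0), expected_tms = 14,
                            len_cutoff = 490, gap_open = 10.0,
                            gap_extend = 0.5, matrix = "BLOSUM62",
                            tree_model = "poisson", tree_root = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$simulate) && (is.null(cfg$fasta) || is.null(cfg$annotations))) {
    abort("either input files (fasta + annotations) or a simulate block is required")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(lapply(unclass(cfg), function(x)
    if (is.null(x)) "" else x)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: `input` (read or simulate proteomes and
#' annotations), `allvsall` (similarity network), `cluster` (global
#' clusters at the conservative and relaxed thresholds, plus a
#' threshold sweep per seed), `topology` (full-size screen), `synteny`
#' (synteny network and lineages), `stats` (per-cluster
#' identity/similarity), `tree` (NJ tree per query cluster of
#' equal-length members). Each stage writes its artifacts once and
#' records them in a manifest (`manifest.tsv`) with row counts and MD5
#' checksums; a rerun with an unchanged configuration skips every stage
#' whose artifacts still match the manifest, and re-executes a stage
#' (and its dependents) whose artifacts are missing or corrupt.
#'
#' @param cfg A [pipeline_config()] (or path to a YAML file).
#' @return The manifest tibble: `stage`, `status`, `artifact`, `rows`,
#'   `md5`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  hash_file <- file.path(cfg$outdir, "config_hash")
  manifest_file <- file.path(cfg$outdir, "manifest.tsv")
  prev <- NULL
  if (file.exists(hash_file) && file.exists(manifest_file) &&
      readLines(hash_file)[1] == hash) {
    prev <- readr::read_tsv(manifest_file, show_col_types = FALSE)
  }
  writeLines(hash, hash_file)

  art <- function(...) file.path(cfg$outdir, ...)
  manifest <- list()
  dirty <- FALSE  # once a stage runs, all dependents run too

  stage_ok <- function(stage, files) {
    if (dirty || is.null(prev)) return(FALSE)
    rows <- prev[prev$stage == stage, ]
    if (nrow(rows) == 0 || !setequal(rows$artifact, basename(files))) {
      return(FALSE)
    }
    if (!all(file.exists(files))) return(FALSE)
    md5 <- unname(tools::md5sum(files))[match(rows$artifact, basename(files))]
    all(md5 == rows$md5)
  }
  record <- function(stage, status, files, rows_per_file) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, status = status, artifact = basename(files),
      rows = rows_per_file, md5 = unname(tools::md5sum(files)))
  }
  run_stage <- function(stage, files, fun) {
    if (stage_ok(stage, files)) {
      rows <- prev$rows[match(basename(files), prev$artifact)]
      record(stage, "skipped", files, rows)
      return(FALSE)
    }
    rows <- tryCatch(fun(), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
    dirty <<- TRUE
    record(stage, "executed", files, rows)
    TRUE
  }

  # ---- input ---------------------------------------------------------
  proteins_file <- art("proteins.faa")
  annotation_file <- art("annotation.tsv")
  input_files <- c(proteins_file, annotation_file)
  universe <- NULL
  run_stage("input", input_files, function() {
    if (!is.null(cfg$simulate)) {
      universe <<- simulate_universe(do.call(simulation_config, cfg$simulate))
      write_fasta(universe$proteins, proteins_file)
      readr::write_tsv(universe$annotation, annotation_file)
      readr::write_tsv(universe$truth, art("truth.tsv"))
    } else {
      prot <- bind_rows(lapply(cfg$fasta, read_fasta))
      ann <- bind_rows(lapply(cfg$annotations, read_annotation))
      write_fasta(prot, proteins_file)
      readr::write_tsv(ann, annotation_file)
    }
    c(length(Biostrings::readAAStringSet(proteins_file)),
      nrow(readr::read_tsv(annotation_file, show_col_types = FALSE)))
  })
  proteins <- read_fasta(proteins_file)
  annotation <- readr::read_tsv(annotation_file, show_col_types = FALSE)

  # ---- all-vs-all ----------------------------------------------------
  hits_file <- art("hits.tsv")
  net <- NULL
  run_stage("allvsall", hits_file, function() {
    scheme <- scoring_scheme()  # BLOSUM62 11/1: supported KA statistics
    # keep everything down to the most permissive exponent of interest
    keep_exp <- max(cfg$cutoff_exponent, cfg$relaxed_exponent, -12)
    net <<- all_vs_all(proteins, scheme, cutoff_exponent = keep_exp)
    write_hit_table(
      tidy(net) |> rename(query = "from", subject = "to") |>
        mutate(bitscore = .data$score),
      hits_file)
    nrow(tidy(net))
  })
  if (is.null(net)) {
    net <- network_from_hits(read_hit_table(hits_file), nodes = proteins$id)
  }

  # ---- clustering ----------------------------------------------------
  cons_file <- art("clusters_conservative.tsv")
  relax_file <- art("clusters_relaxed.tsv")
  sweep_file <- art("threshold_sweep.tsv")
  run_stage("cluster", c(cons_file, relax_file, sweep_file), function() {
    cons <- global_clusters(net, cfg$neighbour_exponent)
    relax <- global_clusters(net, cfg$relaxed_exponent)
    write_clusters(cons, cons_file)
    write_clusters(relax, relax_file)
    sweeps <- purrr::map_dfr(cfg$seeds, function(s) {
      sweep_thresholds(net, s) |> mutate(seed = s)
    })
    if (nrow(sweeps) == 0) {
      sweeps <- tibble(exponent = integer(0), retrieved = integer(0),
                       seed = character(0))
    }
    readr::write_tsv(sweeps, sweep_file)
    c(nrow(cons), nrow(relax), nrow(sweeps))
  })
  clusters_cons <- readr::read_tsv(cons_file, show_col_types = FALSE)
  clusters_relax <- readr::read_tsv(relax_file, show_col_types = FALSE)

  # ---- topology ------------------------------------------------------
  topo_file <- art("topology.tsv")
  run_stage("topology", topo_file, function() {
    topo <- topology_table(proteins, expected_tms = cfg$expected_tms,
                           len_cutoff = cfg$len_cutoff)
    write_topology(topo, topo_file)
    nrow(topo)
  })
  topology <- readr::read_tsv(topo_file, show_col_types = FALSE)

  # ---- synteny + lineages --------------------------------------------
  lineage_file <- art("lineages.tsv")
  evidence_file <- art("synteny_evidence.tsv")
  graphml_file <- art("synteny.graphml")
  run_stage("synteny", c(lineage_file, evidence_file, graphml_file),
            function() {
    queries <- if (length(cfg$seeds) > 0) {
      cnet <- constrain(net, cfg$cutoff_exponent)
      unique(unlist(lapply(cfg$seeds, function(s) traverse(cnet, s))))
    } else {
      proteins$id
    }
    snet <- build_synteny_network(
      queries, annotation, neighbour_clusters = clusters_cons,
      query_clusters = clusters_cons, relaxed_clusters = clusters_relax,
      W = cfg$W, net = net)
    lineages <- infer_lineages(snet)
    write_lineages(lineages, lineage_file)
    readr::write_tsv(edge_report(snet), evidence_file)
    write_synteny_graphml(snet, graphml_file)
    c(nrow(lineages), nrow(snet$evidence), nrow(snet$edges))
  })
  lineages <- readr::read_tsv(lineage_file, show_col_types = FALSE)

  # ---- per-cluster stats ---------------------------------------------
  stats_file <- art("cluster_stats.tsv")
  run_stage("stats", stats_file, function() {
    # summarise the query clusters only (all-gene summaries would be
    # quadratic in the proteome)
    qids <- unique(lineages$gene_id)
    qcl <- filter(clusters_cons, .data$protein_id %in% qids)
    scheme <- scoring_scheme(cfg$matrix, cfg$gap_open, cfg$gap_extend)
    summ <- cluster_summary(qcl, proteins, full_size_only = TRUE,
                            topology = topology, scheme = scheme)
    write_cluster_summary(summ, stats_file)
    nrow(summ)
  })

  # ---- trees ---------------------------------------------------------
  tree_file <- art("trees.nwk")
  run_stage("tree", tree_file, function() {
    qids <- unique(lineages$gene_id)
    qcl <- filter(clusters_cons, .data$protein_id %in% qids)
    seqs <- setNames(proteins$sequence, proteins$id)
    trees <- character(0)
    for (cl in unique(qcl$cluster_label)) {
      ids <- sort(qcl$protein_id[qcl$cluster_label == cl])
      if (length(ids) < 3) next
      s <- seqs[ids]
      if (length(unique(nchar(s))) != 1) next  # needs an external MSA
      D <- distance_from_msa(s, model = cfg$tree_model)
      tr <- neighbor_joining(D)
      if (!is.null(cfg$tree_root) && cfg$tree_root %in% tr$tip.label) {
        tr <- reroot_at(tr, cfg$tree_root)
      }
      trees <- c(trees, ape::write.tree(tr))
    }
    readr::write_lines(trees, tree_file)
    length(trees)
  })

  out <- bind_rows(manifest)
  readr::write_tsv(out, manifest_file)
  out
}
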