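#' Read a protein FASTA file into a tibble of records
#'
#' Sequences are uppercased and trailing stop characters (`*`) stripped.
#' Record IDs follow the pipeline's naming scheme: a lowercase strain
#' acronym (4-6 characters), an underscore, then the gene tag; the strain
#' column is derived from the ID prefix.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `id`, `strain`, `sequence`, `length`.
#'   Only the 20 standard residues plus `X` are accepted; any other
#'   character is an error naming the offending record.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  ids <- names(aa)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad)) {
    abort(paste0("non-amino-acid character in record(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(
    id = unname(ids),
    strain = strain_of(ids),
    sequence = unname(seqs),
    length = nchar(unname(seqs))
  )
}

#' Write protein records to FASTA
#'
#' @param records A tibble with columns `id` and `sequence`
#'   (as produced by [read_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

# strain acronym = id prefix before the first underscore
strain_of <- function(ids) sub("_.*$", "", ids)

#' Read a gene annotation table and assign gene-order ordinals
#'
#' The input is a TSV with header columns `gene_id`, `contig`, `start`,
#' `end`, `strand` (1-based inclusive coordinates). Loci are sorted by
#' (contig, start) and each contig's genes receive consecutive 0-based
#' ordinals in gene order; neighbourhood analysis operates on these
#' ordinals, never on base-pair distances. A `strain` column in the file
#' is carried through if present, otherwise derived from gene IDs.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `ordinal` (plus `strain`), sorted by (contig, start).
#' @export
read_annotation <- function(path) {
  stopifnot(file.exists(path))
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           contig = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           strand = readr::col_character(),
                           .default = readr::col_character()
                         ))
  required <- c("gene_id", "contig", "start", "end", "strand")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    abort(paste0("annotation file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  annotate_loci(ann)
}

#' Sort loci and assign per-contig gene-order ordinals
#'
#' @param ann A data frame with columns `gene_id`, `contig`, `start`,
#'   `end`, `strand`.
#' @return The same rows sorted by (contig, start) with a 0-based
#'   `ordinal` column restarting at each contig.
#' @export
annotate_loci <- function(ann) {
  if (anyDuplicated(ann$gene_id)) {
    abort(paste0("duplicate gene_id: ",
                 paste(unique(ann$gene_id[duplicated(ann$gene_id)]),
                       collapse = ", ")))
  }
  bad <- ann$start > ann$end | ann$start < 1
  if (any(bad)) {
    abort(paste0("invalid coordinates (start > end or start < 1) for: ",
                 paste(ann$gene_id[bad], collapse = ", ")))
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  ann <- as_tibble(ann)
  if (!"strain" %in% names(ann)) {
    ann$strain <- strain_of(ann$gene_id)
  }
  ann |>
    arrange(.data$contig, .data$start, .data$gene_id) |>
    group_by(.data$contig) |>
    mutate(ordinal = seq_len(n()) - 1L) |>
    ungroup()
}

#' Write an annotation tibble as TSV
#'
#' @param ann Annotation tibble (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(ann[, intersect(c("gene_id", "contig", "start", "end",
                                     "strand", "strain"), names(ann))], path)
  invisible(path)
}

#' Read an all-vs-all hit table in 12-column BLAST tabular format
#'
#' Accepts the classic tab-separated dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore), with or
#' without a comment/header line starting with `#`. When the same
#' (query, subject) pair appears more than once, the smallest E-value is
#' kept. Self-hits are retained here; network construction drops them.
#'
#' @param path Path to the hit table.
#' @return A tibble with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  keep <- !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(query = character(), subject = character(),
                  evalue = double(), bitscore = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    abort(sprintf("hit table line %d has %d columns (12 expected)",
                  lineno[i], nf[i]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  tibble(
    query = m[, 1], subject = m[, 2],
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  ) |>
    group_by(.data$query, .data$subject) |>
    summarise(bitscore = .data$bitscore[which.min(.data$evalue)],
              evalue = min(.data$evalue), .groups = "drop") |>
    select("query", "subject", "evalue", "bitscore")
}

#' Write hits in 12-column BLAST tabular format
#'
#' Columns not tracked internally (percent identity, mismatches, gap
#' opens) are written as 0 so the file round-trips through any
#' outfmt-6-compatible reader.
#'
#' @param hits A tibble with columns `query`, `subject`, `evalue` and
#'   either `bitscore` or `score`; optional `q_start`, `q_end`,
#'   `s_start`, `s_end` span columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  n <- nrow(hits)
  grab <- function(col, default) {
    if (col %in% names(hits)) hits[[col]] else rep(default, n)
  }
  out <- tibble(
    qseqid = hits$query, sseqid = hits$subject,
    pident = grab("pident", 0), length = grab("length", 0L),
    mismatch = 0L, gapopen = 0L,
    qstart = grab("q_start", 0L), qend = grab("q_end", 0L),
    sstart = grab("s_start", 0L), send = grab("s_end", 0L),
    evalue = hits$evalue,
    bitscore = if ("bitscore" %in% names(hits)) hits$bitscore
               else grab("score", 0)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
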