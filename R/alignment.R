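#' Define a substitution matrix and affine gap penalties
#'
#' A gap of length L costs `gap_open + L * gap_extend`, the convention
#' used by BLAST; both the local and the global aligner share it.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`) or a named square numeric matrix.
#' @param gap_open Positive gap-opening penalty.
#' @param gap_extend Positive per-residue gap-extension penalty.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  stopifnot(gap_open > 0, gap_extend > 0)
  if (is.character(matrix)) {
    name <- matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    mat <- get(name, envir = env)
  } else {
    name <- "custom"
    mat <- matrix
  }
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            identical(rownames(mat), colnames(mat)))
  # restrict to the pipeline alphabet; X rows exist in the BLOSUM tables
  keep <- intersect(AA_ALPHABET, rownames(mat))
  mat <- mat[keep, keep, drop = FALSE]
  if (!isTRUE(all.equal(mat, t(mat)))) abort("substitution matrix must be symmetric")
  structure(
    list(matrix = mat, matrix_name = name,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s, gap open %g, gap extend %g\n",
              x$matrix_name, x$gap_open, x$gap_extend))
  invisible(x)
}

# Published gapped/ungapped Karlin-Altschul parameters, keyed by
# (matrix, gap_open, gap_extend). Only combinations with established
# values are supported; anything else is an error, never a silent
# fallback.
KA_TABLE <- list(
  "BLOSUM62/11/1" = c(lambda = 0.267, K = 0.041),
  "BLOSUM62/Inf/Inf" = c(lambda = 0.3176, K = 0.134) # ungapped
)

#' Karlin-Altschul parameters for a scoring scheme
#'
#' Looks up the (lambda, K) pair appropriate to the scheme's matrix and
#' gap penalties. The expected number of chance local alignments scoring
#' at least S between sequences of lengths m and n is
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param scheme A [scoring_scheme()].
#' @return An object of class `ka_params` with fields `lambda` and `K`.
#' @export
karlin_altschul <- function(scheme) {
  key <- sprintf("%s/%g/%g", scheme$matrix_name, scheme$gap_open,
                 scheme$gap_extend)
  p <- KA_TABLE[[key]]
  if (is.null(p)) {
    abort(paste0("no Karlin-Altschul parameters available for ", key,
                 "; supported: ", paste(names(KA_TABLE), collapse = ", ")))
  }
  ka_params(p[["lambda"]], p[["K"]])
}

#' Construct Karlin-Altschul parameters directly
#'
#' @param lambda Positive scale parameter.
#' @param K Positive search-space constant.
#' @return An object of class `ka_params`.
#' @export
ka_params <- function(lambda, K) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K), class = "ka_params")
}

#' E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: strictly decreasing in the score
#' and linear in each sequence length.
#'
#' @param score Non-negative raw alignment score (vectorised).
#' @param m,n Lengths of the two sequences.
#' @param ka A [ka_params()] object.
#' @return E-value(s). See [log10_evalue()] for an underflow-safe log10
#'   version used for thresholding.
#' @export
evalue <- function(score, m, n, ka) {
  stopifnot(all(score >= 0))
  ka$K * m * n * exp(-ka$lambda * score)
}

#' log10 E-value (underflow-safe)
#'
#' High scores drive `exp(-lambda * S)` below double precision; all
#' threshold comparisons in the package therefore use log10(E), which
#' stays finite.
#'
#' @inheritParams evalue
#' @return log10 of the E-value(s).
#' @export
log10_evalue <- function(score, m, n, ka) {
  stopifnot(all(score >= 0))
  log10(ka$K) + log10(m) + log10(n) - ka$lambda * score / log(10)
}

# encode sequences as 0-based integer vectors over the matrix alphabet
encode_seqs <- function(seqs, mat) {
  alpha <- rownames(mat)
  lapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    idx <- match(ch, alpha)
    if (anyNA(idx)) abort("sequence contains residues outside the scoring alphabet")
    idx - 1L
  })
}

align_strings <- function(a, b, idx) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  list(
    a = paste(ifelse(idx$a_idx == 0L, "-", ac[pmax(idx$a_idx, 1L)]),
              collapse = ""),
    b = paste(ifelse(idx$b_idx == 0L, "-", bc[pmax(idx$b_idx, 1L)]),
              collapse = "")
  )
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact dynamic programming over the full score matrix; ties between
#' equal-scoring alignments are broken deterministically (first optimal
#' cell in row-major order, traceback preferring substitution over
#' gaps).
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @param scheme A [scoring_scheme()]; default BLOSUM62 with gap open 11,
#'   extend 1.
#' @param ka Optional [ka_params()]; when supplied (or derivable from the
#'   scheme) the hit carries an E-value.
#' @return A `local_hit` list: `score`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `aligned_a`, `aligned_b`, and `evalue`/`log10_evalue` when
#'   statistics are available.
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme(), ka = NULL) {
  if (nchar(a) == 0 || nchar(b) == 0) {
    return(structure(list(score = 0, q_start = NA_integer_,
                          q_end = NA_integer_, s_start = NA_integer_,
                          s_end = NA_integer_, aligned_a = "",
                          aligned_b = ""), class = "local_hit"))
  }
  enc <- encode_seqs(c(a, b), scheme$matrix)
  res <- align_pair_cpp(enc[[1]], enc[[2]], scheme$matrix,
                        scheme$gap_open, scheme$gap_extend, TRUE)
  al <- align_strings(a, b, res)
  hit <- list(score = res$score,
              q_start = res$q_start, q_end = res$q_end,
              s_start = res$s_start, s_end = res$s_end,
              aligned_a = al$a, aligned_b = al$b)
  if (is.null(ka)) {
    ka <- tryCatch(karlin_altschul(scheme), error = function(e) NULL)
  }
  if (!is.null(ka)) {
    hit$evalue <- evalue(res$score, nchar(a), nchar(b), ka)
    hit$log10_evalue <- log10_evalue(res$score, nchar(a), nchar(b), ka)
  }
  structure(hit, class = "local_hit")
}

#' @export
print.local_hit <- function(x, ...) {
  cat(sprintf("<local_hit> score %g, query %s-%s, subject %s-%s\n",
              x$score, x$q_start, x$q_end, x$s_start, x$s_end))
  if (!is.null(x$evalue)) cat(sprintf("  E-value %.3g\n", x$evalue))
  invisible(x)
}

#' Optimal global alignment with percent identity and similarity
#'
#' True global (end gaps penalised) affine-gap alignment in the style of
#' EMBOSS needle, whose default penalties (gap open 10.0, extend 0.5,
#' EBLOSUM62) are the defaults here. Identity is the fraction of
#' identical columns over the full alignment length (gap columns in the
#' denominator); similarity additionally counts substitutions with a
#' positive matrix score.
#'
#' @param a,b Amino-acid sequences (character scalars, non-empty).
#' @param scheme A [scoring_scheme()].
#' @return A `global_alignment` list: `score`, `aligned_a`, `aligned_b`,
#'   `alignment_length`, `identity_pct`, `similarity_pct`.
#' @export
needleman_wunsch <- function(a, b,
                             scheme = scoring_scheme("BLOSUM62", 10.0, 0.5)) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("empty sequence in global alignment")
  enc <- encode_seqs(c(a, b), scheme$matrix)
  res <- align_pair_cpp(enc[[1]], enc[[2]], scheme$matrix,
                        scheme$gap_open, scheme$gap_extend, FALSE)
  al <- align_strings(a, b, res)
  ac <- strsplit(al$a, "", fixed = TRUE)[[1]]
  bc <- strsplit(al$b, "", fixed = TRUE)[[1]]
  len <- length(ac)
  aligned <- ac != "-" & bc != "-"
  ident <- sum(aligned & ac == bc)
  simil <- ident
  sub <- aligned & ac != bc
  if (any(sub)) {
    simil <- simil + sum(scheme$matrix[cbind(ac[sub], bc[sub])] > 0)
  }
  structure(
    list(score = res$score, aligned_a = al$a, aligned_b = al$b,
         alignment_length = len,
         identity_pct = 100 * ident / len,
         similarity_pct = 100 * simil / len),
    class = "global_alignment"
  )
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global_alignment> score %g, length %d, identity %.1f%%, similarity %.1f%%\n",
              x$score, x$alignment_length, x$identity_pct, x$similarity_pct))
  invisible(x)
}

#' All-vs-all local alignment similarity network
#'
#' Aligns every unordered pair of distinct records with the exact local
#' aligner and keeps pairs whose Karlin-Altschul E-value is at most
#' `10^cutoff_exponent`. Because a pair is aligned once with a symmetric
#' matrix, the directional E-values coincide; the stored weight is that
#' single (minimum) E-value. Self comparisons are excluded.
#'
#' @param records Tibble of protein records (see [read_fasta()]).
#' @param scheme A [scoring_scheme()].
#' @param ka [ka_params()]; defaults to the lookup for `scheme`.
#' @param cutoff_exponent Integer E-value exponent; edges with
#'   `E <= 10^cutoff_exponent` are retained (default -15).
#' @return A [similarity_network()] over all record IDs.
#' @export
all_vs_all <- function(records, scheme = scoring_scheme(), ka = NULL,
                       cutoff_exponent = -15) {
  stopifnot(nrow(records) >= 2)
  if (is.null(ka)) ka <- karlin_altschul(scheme)
  ids <- records$id
  enc <- encode_seqs(records$sequence, scheme$matrix)
  scores <- sw_scores_all_cpp(enc, scheme$matrix, scheme$gap_open,
                              scheme$gap_extend)
  n <- length(ids)
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- sequence((n - 1):1, from = 2:n)
  lens <- records$length
  l10 <- log10_evalue(scores, lens[i], lens[j], ka)
  keep <- l10 <= cutoff_exponent
  edges <- tibble(
    from = pmin(ids[i[keep]], ids[j[keep]]),
    to = pmax(ids[i[keep]], ids[j[keep]]),
    score = scores[keep],
    log10_evalue = l10[keep],
    evalue = 10^l10[keep]
  )
  similarity_network(edges, nodes = ids)
}
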