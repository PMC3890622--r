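# Kyte-Doolittle hydropathy index
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

#' Sliding-window hydropathy profile
#'
#' Mean Kyte-Doolittle index over a centred window; position i of the
#' profile is the mean over residues i .. i+window-1, so the profile has
#' `nchar(seq) - window + 1` values. Window 19 is the classic choice for
#' transmembrane helix detection.
#'
#' @param seq Amino-acid sequence (character scalar).
#' @param window Odd window width, at least 3.
#' @return Numeric vector of window means; empty (with a warning) when
#'   the sequence is shorter than the window.
#' @export
hydropathy_profile <- function(seq, window = 19) {
  stopifnot(window >= 3, window %% 2 == 1)
  n <- nchar(seq)
  if (n < window) {
    warn(sprintf("sequence length %d shorter than window %d; empty profile",
                 n, window))
    return(numeric(0))
  }
  vals <- KYTE_DOOLITTLE[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]
  if (anyNA(vals)) abort("sequence contains residues without a hydropathy index")
  cs <- cumsum(c(0, unname(vals)))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

# split a residue span recursively at the interior hydropathy minimum
# until no piece exceeds 2 * max_len; cut points are window centres.
split_span <- function(lo, hi, profile, offset, max_len) {
  if (hi - lo + 1 <= 2 * max_len) return(list(c(lo, hi)))
  ctr_lo <- max(1L, lo - offset + 1L)
  ctr_hi <- min(length(profile), hi - offset - 1L)
  if (ctr_hi <= ctr_lo) {            # no interior profile support: midpoint
    cut <- (lo + hi) %/% 2L
  } else {
    idx <- ctr_lo:ctr_hi
    vals <- profile[idx]
    mins <- idx[vals == min(vals)]
    # among tied minima, cut nearest the span centre (flat runs would
    # otherwise shave off one end repeatedly)
    centre <- (lo + hi) / 2 - offset
    i_min <- mins[which.min(abs(mins - centre))]
    cut <- i_min + offset
  }
  c(split_span(lo, cut - 1L, profile, offset, max_len),
    split_span(cut + 1L, hi, profile, offset, max_len))
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of the profile at or above the threshold become
#' candidate segments. A profile run spanning positions i..j supports
#' the residue span `[i + pad, j + window - 1 - pad]` with
#' `pad = floor((window - 1) / 4)`: a qualifying window vouches for its
#' central half, which keeps consecutive helices separated by short
#' loops from bleeding into each other. Overlapping spans are merged;
#' spans longer than `2 * max_len` are split at the interior hydropathy
#' minimum; spans longer than `max_len` are trimmed to `max_len`
#' (centred); spans shorter than `min_len` are discarded.
#'
#' @param profile Numeric vector from [hydropathy_profile()].
#' @param threshold Hydropathy threshold (default 1.6).
#' @param min_len,max_len Accepted segment length bounds, in residues
#'   (defaults 17 and 25, typical for transmembrane helices).
#' @param window The window used to build the profile (default 19).
#' @return Tibble with columns `start`, `end`: 1-based residue ranges,
#'   non-overlapping and sorted.
#' @export
predict_tms <- function(profile, threshold = 1.6, min_len = 17,
                        max_len = 25, window = 19) {
  empty <- tibble(start = integer(0), end = integer(0))
  if (length(profile) == 0) return(empty)
  above <- profile >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  offset <- (window - 1L) %/% 2L
  pad <- (window - 1L) %/% 4L
  span_lo <- lo[r$values] + pad
  span_hi <- hi[r$values] + window - 1L - pad
  # merge overlapping or touching spans
  merged <- list()
  cur <- c(span_lo[1], span_hi[1])
  for (k in seq_along(span_lo)[-1]) {
    if (span_lo[k] <= cur[2] + 1L) {
      cur[2] <- max(cur[2], span_hi[k])
    } else {
      merged <- c(merged, list(cur))
      cur <- c(span_lo[k], span_hi[k])
    }
  }
  merged <- c(merged, list(cur))
  pieces <- list()
  for (sp in merged) {
    pieces <- c(pieces, split_span(sp[1], sp[2], profile, offset, max_len))
  }
  out <- purrr::map_dfr(pieces, function(p) {
    len <- p[2] - p[1] + 1
    if (len < min_len) return(NULL)
    if (len > max_len) {
      p[1] <- p[1] + (len - max_len) %/% 2
      p[2] <- p[1] + max_len - 1
    }
    tibble(start = as.integer(p[1]), end = as.integer(p[2]))
  })
  if (nrow(out) == 0) empty else arrange(out, .data$start)
}

#' Full-size vs fragment call for a candidate transporter
#'
#' A sequence is full-size when it reaches the length cutoff OR shows
#' (close to) the expected number of transmembrane segments; everything
#' else is a fragment. The disjunction rescues short sequences whose
#' topology is nevertheless complete, and the slack absorbs predictor
#' noise around the expected count.
#'
#' @param length Residue count (vectorised).
#' @param tms_count Predicted TMS count (vectorised).
#' @param expected_tms Expected spans for the family (default 14).
#' @param len_cutoff Full-size length cutoff in residues (default 490).
#' @param slack TMS-count slack (default 2).
#' @return Logical: `TRUE` full-size, `FALSE` fragment.
#' @export
classify_full_size <- function(length, tms_count, expected_tms = 14,
                               len_cutoff = 490, slack = 2) {
  length >= len_cutoff | tms_count >= expected_tms - slack
}

#' Topology screen over a set of protein records
#'
#' Runs the hydropathy predictor on every record and applies the
#' full-size screen. The predictor is an automated stand-in for manual
#' inspection of topology plots, and the output carries a `method`
#' attribute saying so.
#'
#' @param records Tibble of protein records (see [read_fasta()]).
#' @param window,threshold,min_len,max_len Hydropathy predictor
#'   parameters, see [predict_tms()].
#' @param expected_tms,len_cutoff,slack Screen parameters, see
#'   [classify_full_size()].
#' @return Tibble `protein_id`, `length`, `tms_count`, `ranges`
#'   (comma-separated `start-end` pairs), `full_size` (`TRUE`/`FALSE`).
#' @export
topology_table <- function(records, window = 19, threshold = 1.6,
                           min_len = 17, max_len = 25, expected_tms = 14,
                           len_cutoff = 490, slack = 2) {
  rows <- purrr::map2_dfr(records$id, records$sequence, function(id, s) {
    prof <- suppressWarnings(hydropathy_profile(s, window))
    tms <- predict_tms(prof, threshold, min_len, max_len, window)
    tibble(protein_id = id, length = nchar(s), tms_count = nrow(tms),
           ranges = paste(sprintf("%d-%d", tms$start, tms$end),
                          collapse = ","))
  })
  rows$full_size <- classify_full_size(rows$length, rows$tms_count,
                                       expected_tms, len_cutoff, slack)
  attr(rows, "method") <- "automated hydropathy screen (Kyte-Doolittle); stand-in for manual topology-plot inspection"
  rows
}

#' Write a topology table as TSV
#'
#' @param topo Tibble from [topology_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  readr::write_tsv(topo, path)
  invisible(path)
}

#' Plot a hydropathy profile with the TMS threshold
#'
#' @param seq Amino-acid sequence.
#' @param window Window width (default 19).
#' @param threshold Threshold drawn as a reference line (default 1.6).
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(seq, window = 19, threshold = 1.6) {
  prof <- hydropathy_profile(seq, window)
  offset <- (window - 1L) %/% 2L
  df <- tibble(position = seq_along(prof) + offset, hydropathy = prof)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$hydropathy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue (window centre)",
                  y = "mean Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
}
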