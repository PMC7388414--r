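# Mapping identified peptides onto parent sequences: per-residue coverage,
# multi-enzyme consensus N-terminus, full-sequencing checks and comparison
# of observed vs predicted maturation boundaries.

#' Build a per-residue coverage map
#'
#' Tallies how many evidence peptides cover each residue of a parent
#' sequence and, for every peptide start position, which distinct enzymes
#' contributed a peptide beginning there. Duplicate evidence rows count in
#' the depth (they are independent observations) but not in the enzyme
#' support sets.
#'
#' @param evidence Data frame with columns `start`, `end` (1-based
#'   inclusive) and `enzyme`; optionally `parent_id` and `spectra_count`.
#' @param parent_sequence The parent (precursor or mature) sequence.
#' @param parent_id Identifier recorded on the map; defaults to the one in
#'   `evidence` when unique.
#' @return Object of class `coverage_map`: list with `parent_id`, `length`,
#'   `depth` (integer vector), `boundary_support` (named list mapping start
#'   position to the character vector of supporting enzymes) and the
#'   `evidence` intervals used.
#' @export
build_coverage <- function(evidence, parent_sequence, parent_id = NULL) {
  stopifnot(is.data.frame(evidence),
            all(c("start", "end", "enzyme") %in% names(evidence)))
  L <- nchar(parent_sequence)
  if (is.null(parent_id)) {
    parent_id <- if ("parent_id" %in% names(evidence) && nrow(evidence) &&
                     length(unique(evidence$parent_id)) == 1L)
      evidence$parent_id[1L] else NA_character_
  }
  if (nrow(evidence)) {
    bad <- which(evidence$start < 1L | evidence$end > L |
                   evidence$start > evidence$end)
    if (length(bad)) {
      stop(sprintf("evidence out of parent bounds at row(s) %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  depth <- integer(L)
  for (r in seq_len(nrow(evidence))) {
    idx <- evidence$start[r]:evidence$end[r]
    depth[idx] <- depth[idx] + 1L
  }
  support <- lapply(split(evidence$enzyme, evidence$start),
                    function(e) sort(unique(e)))
  structure(
    list(parent_id = parent_id, length = L, depth = depth,
         boundary_support = support,
         evidence = evidence[, c("start", "end", "enzyme")]),
    class = "coverage_map"
  )
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("<coverage_map> %s: %d residues, %d peptides, %.0f%% covered\n",
              x$parent_id, x$length, nrow(x$evidence),
              100 * mean(x$depth > 0)))
  invisible(x)
}

#' Consensus mature N-terminus from multi-enzyme evidence
#'
#' The mature N-terminus is called at the smallest peptide start position
#' supported by at least `min_enzymes` distinct enzymes — the multi-enzyme
#' consensus rule: independent proteases (and the native, undigested
#' channel, which counts as its own enzyme) agreeing on the same first
#' residue. Returns `NA` when no position reaches the threshold
#' (undetermined).
#'
#' @param coverage A [build_coverage()] map.
#' @param min_enzymes Minimum number of distinct supporting enzymes.
#' @return Integer position, or `NA_integer_` if undetermined.
#' @export
consensus_n_terminus <- function(coverage, min_enzymes = 2L) {
  stopifnot(inherits(coverage, "coverage_map"), min_enzymes >= 1L)
  starts <- as.integer(names(coverage$boundary_support))
  n_enz <- vapply(coverage$boundary_support, length, integer(1))
  ok <- starts[n_enz >= min_enzymes]
  if (!length(ok)) NA_integer_ else min(ok)
}

#' Is a span fully sequenced by overlapping fragments?
#'
#' A span counts as fully sequenced only when every residue is covered and
#' consecutive fragments overlap by at least one residue: merely abutting
#' peptides cannot exclude an insertion at their junction, so an
#' overlap-linked chain is required.
#'
#' @param coverage A [build_coverage()] map.
#' @param mature_span Integer `c(start, end)` of the span to check, 1-based
#'   inclusive within the parent.
#' @return List with `fully_sequenced` (logical) and `first_gap` (the first
#'   uncovered or overlap-unlinked position; `NA` when fully sequenced).
#' @export
is_fully_sequenced <- function(coverage, mature_span) {
  stopifnot(inherits(coverage, "coverage_map"), length(mature_span) == 2L)
  s <- as.integer(mature_span[1L]); e <- as.integer(mature_span[2L])
  if (s < 1L || e > coverage$length || s > e) {
    stop("'mature_span' outside parent", call. = FALSE)
  }
  ivl <- coverage$evidence
  ivl <- ivl[ivl$end >= s & ivl$start <= e, , drop = FALSE]
  cand <- ivl[ivl$start <= s, , drop = FALSE]
  if (!nrow(cand)) {
    return(list(fully_sequenced = FALSE, first_gap = s))
  }
  reach <- max(cand$end)
  repeat {
    if (reach >= e) return(list(fully_sequenced = TRUE, first_gap = NA_integer_))
    # extend only through fragments overlapping the covered region >= 1 residue
    nxt <- ivl$start <= reach & ivl$end > reach
    if (!any(nxt)) {
      return(list(fully_sequenced = FALSE, first_gap = reach + 1L))
    }
    reach <- max(ivl$end[nxt])
  }
}

#' Compare observed and predicted maturation boundaries
#'
#' @param predicted_start Predicted 1-based mature start in the precursor
#'   (e.g. from a signal/propeptide predictor).
#' @param observed_start Observed mature start (e.g. the consensus
#'   N-terminus).
#' @param parent_sequence Precursor sequence, used to extract the extension
#'   when the observed mature form is longer than predicted.
#' @return Data frame with `predicted_start`, `observed_start`,
#'   `delta_residues` (`predicted - observed`; positive means the observed
#'   mature peptide is N-terminally longer than predicted) and
#'   `extension_sequence` (the extra residues, empty when none).
#' @export
#' @examples
#' compare_maturation(3, 1, "NREHCYIP")  # delta 2, extension "NR"
compare_maturation <- function(predicted_start, observed_start,
                               parent_sequence) {
  L <- nchar(parent_sequence)
  stopifnot(predicted_start >= 1L, predicted_start <= L,
            observed_start >= 1L, observed_start <= L)
  delta <- as.integer(predicted_start) - as.integer(observed_start)
  ext <- if (delta > 0L) {
    substring(parent_sequence, observed_start, predicted_start - 1L)
  } else ""
  data.frame(predicted_start = as.integer(predicted_start),
             observed_start = as.integer(observed_start),
             delta_residues = delta, extension_sequence = ext,
             stringsAsFactors = FALSE)
}
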