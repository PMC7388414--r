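# Hi3 label-free quantification: top-three peptide abundance, the
# identification filters (>= 3 peptides, >= 2 replicates), and relative
# abundance reporting.

#' Hi3 abundance of one protein in one run
#'
#' The mean signal intensity of the three most intense peptides (all of
#' them when fewer than three were observed). Ties are resolved by sorting
#' on decreasing intensity then increasing sequence, which never changes
#' the mean but makes the selected peptide set deterministic.
#'
#' @param intensities Non-empty numeric vector of peptide intensities.
#' @param sequences Optional character vector of peptide sequences (same
#'   length), used only as the tie-break key.
#' @return The Hi3 abundance.
#' @export
#' @examples
#' hi3(c(10, 8, 5, 1))  # mean(10, 8, 5)
hi3 <- function(intensities, sequences = NULL) {
  if (!length(intensities)) stop("no peptide intensities", call. = FALSE)
  if (any(is.na(intensities) | intensities < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  ord <- if (is.null(sequences)) order(-intensities)
         else order(-intensities, sequences)
  top <- intensities[ord][seq_len(min(3L, length(intensities)))]
  mean(top)
}

#' Identification filters for quantifiable proteins
#'
#' A protein is retained when it was identified with at least
#' `min_peptides` distinct peptides (across replicates) and detected in at
#' least `min_replicates` replicates.
#'
#' @param quant_input Data frame with columns `protein_id`, `replicate_id`,
#'   `peptide_sequence`, `intensity`.
#' @param min_peptides Minimum distinct peptides.
#' @param min_replicates Minimum replicates with any detection.
#' @return Character vector of retained protein ids.
#' @export
apply_filters <- function(quant_input, min_peptides = 3L,
                          min_replicates = 2L) {
  stopifnot(all(c("protein_id", "replicate_id", "peptide_sequence",
                  "intensity") %in% names(quant_input)))
  by_prot <- split(quant_input, quant_input$protein_id)
  keep <- vapply(by_prot, function(d) {
    length(unique(d$peptide_sequence)) >= min_peptides &&
      length(unique(d$replicate_id)) >= min_replicates
  }, logical(1))
  names(by_prot)[keep]
}

#' Relative abundance in percent
#'
#' @param abundances Named non-negative numeric vector (protein to
#'   abundance); at least one value must be positive.
#' @return Named numeric vector of percentages summing to 100.
#' @export
relative_abundance <- function(abundances) {
  if (!length(abundances) || any(is.na(abundances)) || any(abundances < 0)) {
    stop("abundances must be non-negative and non-missing", call. = FALSE)
  }
  tot <- sum(abundances)
  if (tot <= 0) stop("all abundances are zero", call. = FALSE)
  100 * abundances / tot
}

#' Hi3 quantification report
#'
#' Runs the full quantification stage: per-protein distinct-peptide and
#' replicate tallies, per-replicate Hi3, the mean Hi3 over the replicates in
#' which the protein was detected (missing is not zero under
#' data-independent acquisition), the identification filters, and relative
#' abundances over the retained proteins only. Filtered-out proteins stay
#' in the report flagged `retained = FALSE` with `relative_percent = NA`.
#'
#' @inheritParams apply_filters
#' @return Data frame with one row per protein: `protein_id`,
#'   `peptide_count`, `replicates_detected`, `mean_hi3`, `retained`,
#'   `relative_percent`, ordered by decreasing abundance.
#' @export
quantify_proteins <- function(quant_input, min_peptides = 3L,
                              min_replicates = 2L) {
  stopifnot(all(c("protein_id", "replicate_id", "peptide_sequence",
                  "intensity") %in% names(quant_input)))
  by_prot <- split(quant_input, quant_input$protein_id)
  rows <- lapply(by_prot, function(d) {
    per_rep <- vapply(split(d, d$replicate_id), function(r) {
      hi3(r$intensity, r$peptide_sequence)
    }, numeric(1))
    data.frame(
      protein_id = d$protein_id[1L],
      peptide_count = length(unique(d$peptide_sequence)),
      replicates_detected = length(unique(d$replicate_id)),
      mean_hi3 = mean(per_rep),
      stringsAsFactors = FALSE
    )
  })
  rep_tab <- do.call(rbind, rows)
  rownames(rep_tab) <- NULL
  rep_tab$retained <- rep_tab$peptide_count >= min_peptides &
    rep_tab$replicates_detected >= min_replicates
  rep_tab$relative_percent <- NA_real_
  if (any(rep_tab$retained)) {
    rep_tab$relative_percent[rep_tab$retained] <-
      relative_abundance(rep_tab$mean_hi3[rep_tab$retained])
  }
  rep_tab[order(-rep_tab$mean_hi3), , drop = FALSE]
}
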