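# Bioactivity screening decision rules applied to external predictor
# scores. The predictors themselves (antimicrobial and anticancer
# machine-learning tools) are upstream: their scores are inputs.

.check_scores <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop(sprintf("%s score(s) outside [0, 1] at row(s) %s", what,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  x
}

#' Antimicrobial significance flags
#'
#' A predicted activity counts as significant only when its score strictly
#' exceeds the threshold (default 0.8); a score of exactly 0.8 is not
#' significant.
#'
#' @param scores Data frame with a `peptide_id` column and any of
#'   `antibacterial`, `antiviral`, `antifungal` in `[0, 1]` (`NA` allowed
#'   for unscored activities).
#' @param threshold Significance threshold (strict).
#' @return `scores` with added logical columns `<activity>_significant`
#'   (`NA` where the score is missing).
#' @export
amp_significance <- function(scores, threshold = 0.8) {
  stopifnot(is.data.frame(scores), "peptide_id" %in% names(scores))
  acts <- intersect(c("antibacterial", "antiviral", "antifungal"),
                    names(scores))
  if (!length(acts)) stop("no activity score columns found", call. = FALSE)
  for (a in acts) {
    .check_scores(scores[[a]], a)
    scores[[paste0(a, "_significant")]] <- scores[[a]] > threshold
  }
  scores
}

#' Anticancer consensus call
#'
#' A peptide is labelled `"ACP"` only on consensus of the two anticancer
#' predictors: both the random-forest and the support-vector-machine score
#' must strictly exceed the threshold (default 0.5). Missing scores yield
#' `"not-evaluated"`.
#'
#' @param rf_score,svm_score Numeric vectors of predictor scores in
#'   `[0, 1]`.
#' @param threshold Consensus threshold (strict).
#' @return Character vector: `"ACP"`, `"Non-ACP"` or `"not-evaluated"`.
#' @export
#' @examples
#' acp_consensus(c(0.668, 0.479), c(0.926, 0.816))  # "ACP", "Non-ACP"
acp_consensus <- function(rf_score, svm_score, threshold = 0.5) {
  stopifnot(length(rf_score) == length(svm_score))
  .check_scores(rf_score, "rf"); .check_scores(svm_score, "svm")
  out <- ifelse(rf_score > threshold & svm_score > threshold,
                "ACP", "Non-ACP")
  out[is.na(rf_score) | is.na(svm_score)] <- "not-evaluated"
  out
}

#' Full screening verdicts
#'
#' Applies both decision rules to a predictor score table.
#'
#' @param scores Data frame with `peptide_id` and any of `antibacterial`,
#'   `antiviral`, `antifungal`, `rf_acp`, `svm_acp`.
#' @param amp_threshold,acp_threshold Rule thresholds.
#' @return The score table with `<activity>_significant` flags and an
#'   `acp_label` column.
#' @export
screen_toxins <- function(scores, amp_threshold = 0.8, acp_threshold = 0.5) {
  out <- amp_significance(scores, amp_threshold)
  if (all(c("rf_acp", "svm_acp") %in% names(scores))) {
    out$acp_label <- acp_consensus(scores$rf_acp, scores$svm_acp,
                                   acp_threshold)
  } else {
    out$acp_label <- "not-evaluated"
  }
  out
}
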