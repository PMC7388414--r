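# Packaged reference tables: the validated mature toxins of the
# Acanthoscurria rondoniae venom peptidome, the venom protein
# quantification, the bioactivity predictor scores and the anticancer
# composition profiles, shipped as plain TSV so the worked examples and
# tests need no external downloads.

.extdata <- function(file) {
  system.file("extdata", file, package = "venomtox", mustWork = TRUE)
}

#' Validated mature toxins reference table
#'
#' The 18 validated mature toxins (11 cysteine-rich peptides across eight
#' families plus seven short peptides) with their reported monoisotopic
#' masses, disulfide counts, log-intensities and ranks. `reported_mass` is
#' the mass as published, which for some entries is the observed rather
#' than theoretical value; `mass_sequence` plus `modifications` give the
#' form whose theoretical mass corresponds to it (notably the des-Gly
#' C-terminally amidated U2-TRTX-Ar1a and the N-terminally acetylated
#' U1-TRTX-Ar1b). The short peptide reported at 812.40 Da (VLPPLKF)
#' deviates from its theoretical 812.52 Da by ~140 ppm and is flagged
#' `mass_discrepant`.
#'
#' @return Data frame with columns `toxin_id`, `reported_mass`, `sequence`,
#'   `aa`, `ss_bonds`, `log_intensity`, `rank`, `family`, `is_crp`,
#'   `modifications`, `mass_sequence`, `mass_discrepant`.
#' @export
reference_toxins <- function() {
  read_tsv_checked(.extdata("toxins_validated.tsv"), c(
    toxin_id = "character", reported_mass = "numeric",
    sequence = "character", aa = "integer", ss_bonds = "integer",
    log_intensity = "numeric", rank = "integer", family = "character",
    is_crp = "logical", modifications = "character",
    mass_sequence = "character", mass_discrepant = "logical"
  ))
}

#' Venom protein quantification reference table
#'
#' The 33 venom proteins quantified by the Hi3 method with their normalised
#' intensities (NI) and reported percentages.
#'
#' @return Data frame with columns `accession`, `peptide_count`,
#'   `mass_kda`, `description`, `ni`, `reported_percent`.
#' @export
reference_quant <- function() {
  read_tsv_checked(.extdata("venom_protein_quant.tsv"), c(
    accession = "character", peptide_count = "integer", mass_kda = "numeric",
    description = "character", ni = "numeric", reported_percent = "numeric"
  ))
}

#' Bioactivity predictor scores reference table
#'
#' Antimicrobial (antibacterial/antiviral/antifungal) and anticancer
#' (random-forest and support-vector-machine) predictor scores for the 18
#' validated toxins and the six positive-control peptides.
#'
#' @return Data frame with columns `peptide_id`, `role` (`toxin` or
#'   `control`), `is_crp`, `family`, `antibacterial`, `antiviral`,
#'   `antifungal`, `rf_acp`, `svm_acp`.
#' @export
reference_bioactivity <- function() {
  read_tsv_checked(.extdata("bioactivity_scores.tsv"), c(
    peptide_id = "character", role = "character", is_crp = "logical",
    family = "character", antibacterial = "numeric", antiviral = "numeric",
    antifungal = "numeric", rf_acp = "numeric", svm_acp = "numeric"
  ))
}

#' Anticancer peptide composition reference table
#'
#' Reported amino-acid class counts and percentages (Cys excluded for the
#' disulfide-bonded peptides) for the six predicted anticancer peptides.
#'
#' @return Long-format data frame with columns `peptide_id`, `class`,
#'   `count`, `percent`.
#' @export
reference_composition <- function() {
  read_tsv_checked(.extdata("acp_composition.tsv"), c(
    peptide_id = "character", class = "character", count = "integer",
    percent = "numeric"
  ))
}
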