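# Exact peptide mass and m/z arithmetic: monoisotopic residue masses,
# disulfide correction, the modification catalog, and (de)charging.

# Monoisotopic residue (amino-acid residue, i.e. minus water) masses in Da,
# from the standard IUPAC elemental masses. Average masses are carried for
# completeness; the pipeline core uses monoisotopic masses only.
.RESIDUE_MONO <- c(
  G =  57.02146374, A =  71.03711381, S =  87.03202841, P =  97.05276385,
  V =  99.06841395, T = 101.04767847, C = 103.00918496, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

.RESIDUE_AVG <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167,
  V =  99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.MASS_WATER    <- 18.010565
.MASS_PROTON   <- 1.00727646
.MASS_HYDROGEN <- 1.0078250319

#' Residue mass table
#'
#' Monoisotopic and average masses (Da) of the 20 standard amino-acid
#' residues (residue = amino acid minus one water). These masses, together
#' with the constants in [mass_constants()], are the mass basis of the whole
#' package.
#'
#' @return A data frame with columns `residue`, `monoisotopic`, `average`,
#'   one row per standard residue, ordered by monoisotopic mass.
#' @seealso [mass_constants()], [monoisotopic_mass()]
#' @export
#' @examples
#' residue_mass_table()
residue_mass_table <- function() {
  ord <- order(.RESIDUE_MONO)
  data.frame(
    residue      = names(.RESIDUE_MONO)[ord],
    monoisotopic = unname(.RESIDUE_MONO[ord]),
    average      = unname(.RESIDUE_AVG[ord]),
    stringsAsFactors = FALSE
  )
}

#' Fixed mass constants
#'
#' @return Named list with monoisotopic masses (Da) of `water`, the `proton`
#'   and the `hydrogen` atom.
#' @export
mass_constants <- function() {
  list(water = .MASS_WATER, proton = .MASS_PROTON, hydrogen = .MASS_HYDROGEN)
}

#' Modification catalog
#'
#' The post-translational and sample-preparation modifications recognised by
#' the mass model. Carbamidomethylation of Cys is a fixed modification of
#' reduced/alkylated digest samples only and is never applied to native
#' mature masses; C-terminal amidation is applied only when annotated on a
#' toxin record, never inferred.
#'
#' @return Data frame with columns `name`, `target` (residue code, `N-term`
#'   or `C-term`), `delta` (Da, signed) and `mode`.
#' @export
modification_catalog <- function() {
  data.frame(
    name   = c("carbamidomethyl", "oxidation", "deamidation", "acetylation",
               "amidation"),
    target = c("C", "M", "N/Q", "N-term", "C-term"),
    delta  = c(57.021464, 15.994915, 0.984016, 42.010565, -0.984016),
    mode   = c("fixed", "variable", "variable", "variable",
               "annotation-driven"),
    stringsAsFactors = FALSE
  )
}

# split a sequence into residues, rejecting non-standard characters with
# the offending position
.residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  }
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(aa %in% names(.RESIDUE_MONO)))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  aa
}

#' Monoisotopic mass of a (modified) peptide
#'
#' Computes the neutral monoisotopic mass as the sum of residue masses plus
#' one water, minus two hydrogen atoms per disulfide bond, plus the mass
#' deltas of any applied modifications. Each element of `modifications` is
#' one applied instance (repeat a name to apply it twice).
#'
#' @param sequence Peptide sequence, one-letter codes of the 20 standard
#'   amino acids.
#' @param ss_bonds Number of disulfide bonds; must not exceed the number of
#'   Cys pairs in the sequence.
#' @param modifications Character vector of modification names from
#'   [modification_catalog()], one per applied instance; `NULL` for none.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("VPPILKY")                       # 828.51
#' monoisotopic_mass("ACGSFMWKCSERLPCCQEYVCSPQWKWCQNP", ss_bonds = 3)
monoisotopic_mass <- function(sequence, ss_bonds = 0L, modifications = NULL) {
  aa <- .residues(sequence)
  if (length(ss_bonds) != 1L || is.na(ss_bonds) || ss_bonds < 0 ||
      ss_bonds != round(ss_bonds)) {
    stop("'ss_bonds' must be a single non-negative integer", call. = FALSE)
  }
  n_cys <- sum(aa == "C")
  if (2L * ss_bonds > n_cys) {
    stop(sprintf("ss_bonds = %d requires %d Cys but sequence has %d",
                 ss_bonds, 2L * ss_bonds, n_cys), call. = FALSE)
  }
  delta <- 0
  if (length(modifications)) {
    cat_tab <- modification_catalog()
    unknown <- setdiff(modifications, cat_tab$name)
    if (length(unknown)) {
      stop("unknown modification(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    delta <- sum(cat_tab$delta[match(modifications, cat_tab$name)])
  }
  sum(.RESIDUE_MONO[aa]) + .MASS_WATER - 2 * ss_bonds * .MASS_HYDROGEN + delta
}

#' m/z of a protonated ion
#'
#' `mz = (M + z * m_proton) / z` for a neutral mass `M` carrying `z` protons.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (vectorised).
#' @param charge Positive integer charge state (vectorised).
#' @return m/z values.
#' @seealso [mass_from_mz()]
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  if (any(is.na(charge)) || any(charge < 1) || any(charge != round(charge))) {
    stop("'charge' must be a positive integer", call. = FALSE)
  }
  if (any(is.na(neutral_mass)) || any(neutral_mass <= 0)) {
    stop("'neutral_mass' must be positive", call. = FALSE)
  }
  (neutral_mass + charge * .MASS_PROTON) / charge
}

#' Neutral mass from an observed m/z
#'
#' Inverse of [mz_from_mass()]: `M = z * (mz - m_proton)`.
#'
#' @param mz Observed m/z (vectorised); must exceed the proton mass.
#' @param charge Positive integer charge state (vectorised).
#' @return Neutral masses in Da.
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(is.na(charge)) || any(charge < 1) || any(charge != round(charge))) {
    stop("'charge' must be a positive integer", call. = FALSE)
  }
  if (any(is.na(mz)) || any(mz <= .MASS_PROTON)) {
    stop("'mz' must exceed the proton mass (non-physical ion)", call. = FALSE)
  }
  charge * (mz - .MASS_PROTON)
}
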