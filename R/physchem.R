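# Physicochemical profiling: Henderson-Hasselbalch net charge and charge
# curves, isoelectric point by bisection, and amino-acid class composition
# with the Cys-exclusion convention for disulfide-bonded peptides.

# Default pKa set. The values reproduce the reported net charges of the
# validated cysteine-rich toxins at pH 7.4 within rounding; other published
# scales shift individual charges by up to ~0.3 units.
.PKA_SCALES <- list(
  default = c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
              D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
  lehninger = c(Nterm = 9.69, Cterm = 2.34, K = 10.5, R = 12.4, H = 6.0,
                D = 3.86, E = 4.25, C = 8.33, Y = 10.0)
)

# residue class alphabets used for composition reports
.AA_CLASSES <- list(
  tiny        = c("A", "C", "G", "S", "T"),
  small       = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
  aliphatic   = c("A", "I", "L", "V"),
  aromatic    = c("F", "H", "W", "Y"),
  hydrophobic = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y"),
  hydrophilic = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
  charged     = c("D", "E", "H", "K", "R"),
  cationic    = c("H", "K", "R"),
  anionic     = c("D", "E")
)

# round half up, as composition percentages are reported
.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Ionizable-group model for charge calculations
#'
#' Bundles a pKa scale with the exclusion conventions used for
#' disulfide-bonded peptides: with `exclude_cys = TRUE` (the convention for
#' cysteine-rich toxins, whose Cys thiols are engaged in disulfide bonds and
#' cannot titrate) Cys residues are removed from the calculation entirely.
#'
#' @param scale Name of a packaged pKa scale (`"default"` or `"lehninger"`)
#'   or a named numeric vector with entries `Nterm`, `Cterm`, `K`, `R`,
#'   `H`, `D`, `E`, `C`, `Y`.
#' @param exclude_cys Exclude Cys residues from charge (and composition)
#'   calculations.
#' @param include_termini Include the alpha-amino and alpha-carboxyl
#'   termini as ionizable groups.
#' @return Object of class `charge_model`.
#' @export
charge_model <- function(scale = "default", exclude_cys = TRUE,
                         include_termini = TRUE) {
  pka <- if (is.character(scale)) {
    if (!scale %in% names(.PKA_SCALES)) {
      stop("unknown pKa scale '", scale, "'", call. = FALSE)
    }
    .PKA_SCALES[[scale]]
  } else scale
  needed <- c("Nterm", "Cterm", "K", "R", "H", "D", "E", "C", "Y")
  if (!all(needed %in% names(pka))) {
    stop("pKa set must name: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(pka <= 0 | pka >= 14)) stop("pKa values must lie in (0, 14)",
                                      call. = FALSE)
  structure(list(pka = pka[needed], exclude_cys = isTRUE(exclude_cys),
                 include_termini = isTRUE(include_termini),
                 scale = if (is.character(scale)) scale else "custom"),
            class = "charge_model")
}

#' @export
print.charge_model <- function(x, ...) {
  cat(sprintf("<charge_model> scale '%s'%s%s\n", x$scale,
              if (x$exclude_cys) ", Cys excluded" else "",
              if (!x$include_termini) ", termini excluded" else ""))
  print(x$pka)
  invisible(x)
}

.effective_residues <- function(sequence, model) {
  aa <- .residues(sequence)
  if (model$exclude_cys) aa <- aa[aa != "C"]
  if (!length(aa)) {
    stop("sequence empty after exclusions", call. = FALSE)
  }
  aa
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch net charge: each basic group (N-terminus, Lys,
#' Arg, His) contributes `1 / (1 + 10^(pH - pKa))` and each acidic group
#' (C-terminus, Asp, Glu, Cys, Tyr) contributes `-1 / (1 + 10^(pKa - pH))`,
#' subject to the model's exclusion flags.
#'
#' @param sequence Peptide sequence.
#' @param pH pH value(s); vectorised.
#' @param model A [charge_model()].
#' @return Net charge, one value per element of `pH`.
#' @export
#' @examples
#' net_charge("KKDDE", 7.4, charge_model())
net_charge <- function(sequence, pH = 7.4, model = charge_model()) {
  aa <- .effective_residues(sequence, model)
  pka <- model$pka
  basics <- pka[aa[aa %in% c("K", "R", "H")]]
  acids <- pka[aa[aa %in% c("D", "E", "Y", if (!model$exclude_cys) "C")]]
  if (model$include_termini) {
    basics <- c(basics, pka["Nterm"])
    acids <- c(acids, pka["Cterm"])
  }
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - basics))) - sum(1 / (1 + 10^(acids - p)))
  }, numeric(1))
}

#' Net-charge curve over a pH range
#'
#' @param sequence Peptide sequence.
#' @param pH_min,pH_max,step pH grid; the defaults (0 to 14 in 0.5 steps)
#'   give a 29-point curve.
#' @param model A [charge_model()].
#' @return Data frame with columns `pH` and `charge`; the charge is
#'   non-increasing along the grid.
#' @export
charge_curve <- function(sequence, pH_min = 0, pH_max = 14, step = 0.5,
                         model = charge_model()) {
  stopifnot(step > 0, pH_max >= pH_min)
  pH <- pH_min + step * seq.int(0L, floor((pH_max - pH_min) / step))
  data.frame(pH = pH, charge = net_charge(sequence, pH, model))
}

#' Isoelectric point
#'
#' The pH at which the net charge vanishes, found by bisection; unique
#' because the charge is strictly decreasing in pH. Undefined (returns
#' `NA`) when the effective sequence lacks either a basic or an acidic
#' group, in which case the charge never crosses zero.
#'
#' @param sequence Peptide sequence.
#' @param model A [charge_model()].
#' @param digits Decimal places of the reported pH.
#' @return The pI (numeric), or `NA_real_` when undefined.
#' @export
#' @examples
#' isoelectric_point("A")  # 6.10, midpoint of the terminal pKas
isoelectric_point <- function(sequence, model = charge_model(), digits = 2L) {
  aa <- .effective_residues(sequence, model)
  n_basic <- sum(aa %in% c("K", "R", "H")) + model$include_termini
  n_acid <- sum(aa %in% c("D", "E", "Y", if (!model$exclude_cys) "C")) +
    model$include_termini
  if (n_basic == 0L || n_acid == 0L) return(NA_real_)
  lo <- 0; hi <- 14
  f_lo <- net_charge(sequence, lo, model)
  f_hi <- net_charge(sequence, hi, model)
  if (f_lo <= 0 || f_hi >= 0) return(NA_real_)  # no sign change in range
  repeat {
    mid <- (lo + hi) / 2
    f <- net_charge(sequence, mid, model)
    if (abs(f) < 1e-4 || (hi - lo) < 1e-8) break
    if (f > 0) lo <- mid else hi <- mid
  }
  round(mid, digits)
}

#' Amino-acid class composition
#'
#' Counts and percentages of residue classes (tiny, small, aliphatic,
#' aromatic, hydrophobic, hydrophilic, charged, cationic, anionic) over the
#' residues considered. With `exclude_cys = TRUE` the Cys residues of
#' disulfide-bonded peptides are removed before counting, so the
#' denominator is the Cys-free length. Hydrophobic and hydrophilic classes
#' partition the (post-exclusion) alphabet, so their counts always sum to
#' the considered length; charged = cationic + anionic + His.
#'
#' @param sequence Peptide sequence.
#' @param exclude_cys Remove Cys residues before counting.
#' @return Data frame with columns `class`, `count`, `percent` (half-up
#'   rounded to 1 decimal), plus attribute `considered_length`.
#' @export
#' @examples
#' aa_composition("PLPVFV", exclude_cys = FALSE)
aa_composition <- function(sequence, exclude_cys = TRUE) {
  aa <- .residues(sequence)
  if (exclude_cys) aa <- aa[aa != "C"]
  if (!length(aa)) stop("sequence empty after Cys exclusion", call. = FALSE)
  n <- length(aa)
  counts <- vapply(.AA_CLASSES, function(cl) sum(aa %in% cl), integer(1))
  out <- data.frame(class = names(.AA_CLASSES), count = unname(counts),
                    percent = .round_half_up(100 * unname(counts) / n, 1L),
                    stringsAsFactors = FALSE)
  attr(out, "considered_length") <- n
  out
}
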