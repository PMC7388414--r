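# Seeded synthetic-data generator: toxin precursors with
# signal/propeptide/mature architecture, multi-enzyme digest evidence with
# dropout, and native precursor-ion maps with ppm jitter, charge-state
# spread, intensity noise and decoy ions.

# residue sampling weights (non-Cys). CRP matures are sampled with elevated
# K/R (cationic) content, the hallmark of venom cysteine-rich peptides;
# short venom peptides are hydrophobic-rich.
.CRP_AA_WEIGHTS <- c(
  A = 0.06, D = 0.06, E = 0.07, F = 0.03, G = 0.08, H = 0.02, I = 0.04,
  K = 0.12, L = 0.06, M = 0.02, N = 0.04, P = 0.05, Q = 0.03, R = 0.08,
  S = 0.08, T = 0.05, V = 0.06, W = 0.02, Y = 0.03
)
.SHORT_AA_WEIGHTS <- c(
  P = 0.20, V = 0.20, L = 0.15, F = 0.12, I = 0.08, Y = 0.08, K = 0.07,
  E = 0.05, T = 0.05
)
.SIGNAL_AA <- c("A", "L", "V", "I", "F", "S", "T", "G")

#' Configuration of the synthetic venom generator
#'
#' Defaults emulate the study conditions the pipeline targets: seven
#' cysteine-rich peptide (CRP) families with 3-5 disulfide bonds and
#' masses in the 3-9 kDa window, seven short hydrophobic peptides below
#' 1.5 kDa, five-enzyme digests with at most two missed cleavages and one
#' nonspecific terminus, 15% per-peptide dropout, ion m/z jitter well
#' inside the 10 ppm matching tolerance, charge states spread over +2..+9,
#' log-normal intensities straddling the 5.0e5 reporting threshold, and
#' decoy ions offset at least 50 ppm (five times the matching tolerance)
#' from every true mass so they are unambiguous negatives.
#'
#' @param seed Integer seed; all generator stages derive their random
#'   streams from it.
#' @param n_crp,n_short Numbers of CRPs and short peptides.
#' @param cys_count_range Even Cys counts for CRPs, inclusive range.
#' @param crp_length_range,short_length_range Mature-length ranges.
#' @param dropout_prob Per-peptide Bernoulli dropout of digest evidence.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param mz_jitter_ppm Uniform m/z jitter half-width in ppm.
#' @param charge_range Charge states emitted for true ions.
#' @param ions_per_toxin Ions emitted per toxin.
#' @param n_decoy_ions Number of decoy ions.
#' @param decoy_min_offset_ppm Minimum ppm offset of decoy masses from
#'   every true mass; must exceed the matching tolerance in use.
#' @param unknown_charge_prob Fraction of decoy ions emitted with unknown
#'   (zero) charge.
#' @param max_missed,max_nonspecific Digest settings for evidence
#'   simulation.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_crp = 7L, n_short = 7L,
                             cys_count_range = c(6L, 10L),
                             crp_length_range = c(30L, 62L),
                             short_length_range = c(5L, 9L),
                             dropout_prob = 0.15,
                             intensity_meanlog = 15, intensity_sdlog = 1.5,
                             mz_jitter_ppm = 5, charge_range = c(2L, 9L),
                             ions_per_toxin = 3L, n_decoy_ions = 50L,
                             decoy_min_offset_ppm = 50,
                             unknown_charge_prob = 0.05,
                             max_missed = 2L, max_nonspecific = 1L) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1,
            unknown_charge_prob >= 0, unknown_charge_prob <= 1,
            mz_jitter_ppm >= 0, decoy_min_offset_ppm > 0,
            cys_count_range[1L] >= 2L,
            cys_count_range[2L] >= cys_count_range[1L],
            n_crp >= 0L, n_short >= 0L, ions_per_toxin >= 1L)
  if (cys_count_range[2L] > crp_length_range[1L]) {
    stop("infeasible: maximum Cys count exceeds minimum CRP length",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

.sample_seq <- function(n, weights) {
  paste(sample(names(weights), n, replace = TRUE, prob = weights),
        collapse = "")
}

# sample a CRP mature sequence: non-Cys backbone + Cys placed at random
# positions, resampled until the disulfide-corrected mass is 3-9 kDa
.sample_crp <- function(config) {
  for (attempt in 1:200) {
    len <- sample(config$crp_length_range[1L]:config$crp_length_range[2L], 1L)
    evens <- seq(config$cys_count_range[1L], config$cys_count_range[2L],
                 by = 2L)
    n_cys <- if (length(evens) == 1L) evens else sample(evens, 1L)
    backbone <- strsplit(.sample_seq(len - n_cys, .CRP_AA_WEIGHTS), "")[[1L]]
    pos <- sort(sample(len, n_cys))
    aa <- character(len)
    aa[pos] <- "C"
    aa[-pos] <- backbone
    seq <- paste(aa, collapse = "")
    ss <- n_cys %/% 2L
    m <- monoisotopic_mass(seq, ss)
    if (m >= 3000 && m <= 9000) return(list(seq = seq, ss = ss, mass = m))
  }
  stop("could not sample a CRP in the 3-9 kDa window", call. = FALSE)
}

.sample_short <- function(config) {
  for (attempt in 1:200) {
    len <- sample(config$short_length_range[1L]:config$short_length_range[2L],
                  1L)
    seq <- .sample_seq(len, .SHORT_AA_WEIGHTS)
    m <- monoisotopic_mass(seq, 0L)
    if (m < 1500) return(list(seq = seq, ss = 0L, mass = m))
  }
  stop("could not sample a short peptide below 1.5 kDa", call. = FALSE)
}

#' Generate synthetic toxin ground truth
#'
#' Builds precursors with the canonical architecture signal peptide +
#' propeptide + mature toxin. The propeptide ends in an Arg-terminated
#' processing motif (`...ER`), so the mature start is well defined.
#' Reproducible: the same config (seed) always yields the same truth.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `ground_truth`: data frame with one row per
#'   toxin (`id`, `precursor`, `signal_end`, `propeptide_end`,
#'   `mature_start`, `mature`, `ss_bonds`, `true_mass`, `is_crp`).
#' @export
generate_toxins <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_crp + config$n_short
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    is_crp <- i <= config$n_crp
    mat <- if (is_crp) .sample_crp(config) else .sample_short(config)
    signal <- paste0("M", .sample_seq(sample(14:24, 1L),
                                      stats::setNames(rep(1, length(.SIGNAL_AA)),
                                                      .SIGNAL_AA)))
    pro_len <- sample(8:20, 1L)
    pro <- paste0(.sample_seq(pro_len - 2L, .CRP_AA_WEIGHTS), "ER")
    precursor <- paste0(signal, pro, mat$seq)
    rows[[i]] <- data.frame(
      id = sprintf("%s%02d", if (is_crp) "CRP" else "SP",
                   if (is_crp) i else i - config$n_crp),
      precursor = precursor,
      signal_end = nchar(signal),
      propeptide_end = nchar(signal) + nchar(pro),
      mature_start = nchar(signal) + nchar(pro) + 1L,
      mature = mat$seq, ss_bonds = mat$ss, true_mass = mat$mass,
      is_crp = is_crp, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Simulate multi-enzyme digest evidence
#'
#' Digests every mature sequence with each of the five catalog enzymes
#' (missed cleavages and semi-specific expansion per the config), maps the
#' peptides into precursor coordinates, and drops each peptide
#' independently with probability `dropout_prob`.
#'
#' @param truth A [generate_toxins()] result.
#' @param config The same [synthetic_config()].
#' @return Data frame of peptide evidence: `parent_id`, `start`, `end`
#'   (1-based in the precursor), `sequence`, `enzyme`, `spectra_count`.
#' @export
simulate_evidence <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  catalog <- enzyme_catalog()
  out <- list()
  for (i in seq_len(nrow(truth))) {
    off <- truth$mature_start[i] - 1L
    for (rule in catalog) {
      pep <- digest(truth$mature[i], rule, config$max_missed,
                    config$max_nonspecific)
      if (!nrow(pep)) next
      keep <- stats::runif(nrow(pep)) >= config$dropout_prob
      pep <- pep[keep, , drop = FALSE]
      if (!nrow(pep)) next
      out[[length(out) + 1L]] <- data.frame(
        parent_id = truth$id[i], start = pep$start + off,
        end = pep$end + off, sequence = pep$sequence, enzyme = pep$enzyme,
        spectra_count = 1L + stats::rpois(nrow(pep), 1),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(parent_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      enzyme = character(), spectra_count = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a native precursor-ion map
#'
#' Emits `ions_per_toxin` ions per toxin at charge states drawn from the
#' configured range (capped to physically plausible m/z for light
#' peptides), with uniform m/z jitter of at most `mz_jitter_ppm`, log-normal
#' intensities (some falling below the 5.0e5 reporting threshold, so
#' filtering is exercised), plus `n_decoy_ions` decoys whose neutral masses
#' are at least `decoy_min_offset_ppm` away from every true mass; a
#' fraction of the decoys carries unknown (zero) charge.
#'
#' @param truth A [generate_toxins()] result.
#' @param config The same [synthetic_config()].
#' @return Data frame of precursor ions: `run_id`, `mz`, `charge`,
#'   `intensity`, `rt`, plus ground-truth annotations `toxin_id` (`NA` for
#'   decoys) and `is_decoy`.
#' @export
simulate_ion_map <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(config$seed + 2L)
  zr <- config$charge_range
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    m <- truth$true_mass[i]
    z_hi <- max(zr[1L], min(zr[2L], ceiling(m / 800)))
    z <- sample(rep(zr[1L]:z_hi, 2L), config$ions_per_toxin, replace = TRUE)
    jit <- stats::runif(config$ions_per_toxin, -config$mz_jitter_ppm,
                        config$mz_jitter_ppm) * 1e-6
    rows[[i]] <- data.frame(
      run_id = "sim1", mz = mz_from_mass(m, z) * (1 + jit), charge = z,
      intensity = stats::rlnorm(config$ions_per_toxin,
                                config$intensity_meanlog,
                                config$intensity_sdlog),
      rt = stats::runif(config$ions_per_toxin, 10, 60),
      toxin_id = truth$id[i], is_decoy = FALSE, stringsAsFactors = FALSE
    )
  }
  if (config$n_decoy_ions > 0L) {
    masses <- numeric(0)
    while (length(masses) < config$n_decoy_ions) {
      cand <- stats::runif(config$n_decoy_ions, 500, 9500)
      ok <- vapply(cand, function(x) {
        all(abs(x - truth$true_mass) / truth$true_mass * 1e6 >=
              config$decoy_min_offset_ppm)
      }, logical(1))
      masses <- c(masses, cand[ok])
    }
    masses <- masses[seq_len(config$n_decoy_ions)]
    z <- sample(1:6, config$n_decoy_ions, replace = TRUE)
    mz <- mz_from_mass(masses, z)
    unknown <- stats::runif(config$n_decoy_ions) < config$unknown_charge_prob
    z[unknown] <- 0L
    rows[[length(rows) + 1L]] <- data.frame(
      run_id = "sim1", mz = mz, charge = z,
      intensity = stats::rlnorm(config$n_decoy_ions,
                                config$intensity_meanlog,
                                config$intensity_sdlog),
      rt = stats::runif(config$n_decoy_ions, 10, 60),
      toxin_id = NA_character_, is_decoy = TRUE, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
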