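# In silico proteolysis: enzyme specificity rules, cleavage-site scanning,
# and peptide enumeration with missed-cleavage and semi-specific expansion.

#' Construct a protease cleavage rule
#'
#' A rule is data: the cleavage side relative to the target residue, the
#' target residue set, and residues on the far side of the bond that block
#' cleavage (the conventional proline block for trypsin and chymotrypsin).
#'
#' @param name Enzyme name (unique within a catalog).
#' @param side `"C"` to cleave C-terminal of a target residue, `"N"` to
#'   cleave N-terminal of it.
#' @param targets Character vector of target residues.
#' @param blocked_by_next Residues that suppress cleavage when they occupy
#'   the far side of the scissile bond; empty vector for none.
#' @return An object of class `enzyme_rule`.
#' @export
enzyme_rule <- function(name, side = c("C", "N"), targets,
                        blocked_by_next = character()) {
  side <- match.arg(side)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(targets), length(targets) >= 1L)
  structure(
    list(name = name, side = side, targets = unique(targets),
         blocked_by_next = unique(blocked_by_next)),
    class = "enzyme_rule"
  )
}

#' @export
print.enzyme_rule <- function(x, ...) {
  side <- if (x$side == "C") "C-terminal of" else "N-terminal of"
  cat(sprintf("<enzyme_rule> %s: cleaves %s {%s}", x$name, side,
              paste(x$targets, collapse = ",")))
  if (length(x$blocked_by_next)) {
    cat(sprintf(", blocked by next {%s}",
                paste(x$blocked_by_next, collapse = ",")))
  }
  cat("\n")
  invisible(x)
}

#' Catalog of the five digestion enzymes
#'
#' Specificities used throughout the pipeline: trypsin (after K/R, not
#' before P), chymotrypsin (after F/W/Y/L, not before P), Glu-C (after E and
#' D in phosphate buffer, the buffer used for the Glu-C aliquot; set
#' `glu_c = "E"` for the bicarbonate-buffer specificity), Asp-N (before D)
#' and thermolysin (before I/L/V/A/M/F). Every rule is plain data and can be
#' overridden by building rules with [enzyme_rule()].
#'
#' @param glu_c `"ED"` (default, phosphate-buffer specificity) or `"E"`.
#' @return Named list of five [enzyme_rule()] objects.
#' @export
#' @examples
#' enzyme_catalog()$trypsin
enzyme_catalog <- function(glu_c = c("ED", "E")) {
  glu_c <- match.arg(glu_c)
  list(
    trypsin      = enzyme_rule("trypsin", "C", c("K", "R"), "P"),
    chymotrypsin = enzyme_rule("chymotrypsin", "C", c("F", "W", "Y", "L"), "P"),
    `glu-c`      = enzyme_rule("glu-c", "C",
                               if (glu_c == "ED") c("E", "D") else "E"),
    `asp-n`      = enzyme_rule("asp-n", "N", "D"),
    thermolysin  = enzyme_rule("thermolysin", "N",
                               c("I", "L", "V", "A", "M", "F"))
  )
}

#' Cleavage sites of an enzyme on a sequence
#'
#' Inter-residue coordinates: position `i` denotes the bond between residues
#' `i` and `i + 1`. The termini (0 and the sequence length) are implicit and
#' never returned.
#'
#' @param sequence Peptide/protein sequence.
#' @param rule An [enzyme_rule()].
#' @return Strictly increasing integer vector of cleavage positions in
#'   `1 .. nchar(sequence) - 1` (possibly empty).
#' @export
#' @examples
#' cleavage_sites("GRAAKAPK", enzyme_catalog()$trypsin)  # 2, 5
cleavage_sites <- function(sequence, rule) {
  stopifnot(inherits(rule, "enzyme_rule"))
  aa <- .residues(sequence)
  L <- length(aa)
  if (L < 2L) return(integer())
  pos <- seq_len(L - 1L)
  if (rule$side == "C") {
    hit <- aa[pos] %in% rule$targets & !(aa[pos + 1L] %in% rule$blocked_by_next)
  } else {
    hit <- aa[pos + 1L] %in% rule$targets & !(aa[pos] %in% rule$blocked_by_next)
  }
  pos[hit]
}

#' Digest a sequence in silico
#'
#' Enumerates digest peptides of one enzyme. Fully specific peptides span at
#' most `max_missed` internal cleavage sites; with `max_nonspecific = 1`,
#' semi-specific peptides (exactly one terminus truncated away from a
#' cleavage boundary) are added, matching identification-software settings
#' of at most one nonspecific cleavage.
#'
#' @param sequence Parent sequence.
#' @param rule An [enzyme_rule()].
#' @param max_missed Maximum internal (missed) cleavage sites per peptide.
#' @param max_nonspecific 0 or 1 nonspecific termini.
#' @param length_range Length bounds `c(min, max)` applied to reported
#'   peptides; defaults to unrestricted.
#' @param mass_range Monoisotopic mass bounds `c(min, max)` in Da; defaults
#'   to unrestricted.
#' @return Data frame with columns `sequence`, `start`, `end` (1-based
#'   inclusive in the parent), `missed_cleavages`, `nonspecific_termini`,
#'   `enzyme`; one row per distinct peptide position.
#' @export
#' @examples
#' digest("GRAAKAPK", enzyme_catalog()$trypsin, max_missed = 0,
#'        max_nonspecific = 0)
digest <- function(sequence, rule, max_missed = 2L, max_nonspecific = 1L,
                   length_range = c(1L, Inf), mass_range = c(0, Inf)) {
  stopifnot(inherits(rule, "enzyme_rule"), max_missed >= 0,
            max_nonspecific %in% c(0L, 1L))
  aa <- .residues(sequence)
  L <- length(aa)
  sites <- cleavage_sites(sequence, rule)
  cut <- c(0L, sites, L)
  k <- length(cut)

  starts <- integer(0); ends <- integer(0); nonspec <- integer(0)
  # fully specific: spans between cut points with <= max_missed internal sites
  for (i in seq_len(k - 1L)) {
    jmax <- min(k, i + 1L + max_missed)
    for (j in seq.int(i + 1L, jmax)) {
      starts <- c(starts, cut[i] + 1L)
      ends   <- c(ends, cut[j])
      nonspec <- c(nonspec, 0L)
    }
  }
  if (max_nonspecific >= 1L) {
    spec_s <- starts; spec_e <- ends
    for (p in seq_along(spec_s)) {
      a <- spec_s[p]; b <- spec_e[p]
      # truncate the N-terminus: new start a2 with a2-1 not a boundary
      a2 <- setdiff(seq.int(a + 1L, length.out = max(0L, b - a)),
                    cut + 1L)
      if (length(a2)) {
        starts <- c(starts, a2); ends <- c(ends, rep.int(b, length(a2)))
        nonspec <- c(nonspec, rep.int(1L, length(a2)))
      }
      # truncate the C-terminus: new end b2 not a boundary
      b2 <- setdiff(seq.int(a, length.out = max(0L, b - a)), cut)
      if (length(b2)) {
        starts <- c(starts, rep.int(a, length(b2))); ends <- c(ends, b2)
        nonspec <- c(nonspec, rep.int(1L, length(b2)))
      }
    }
  }
  keep <- !duplicated(cbind(starts, ends))
  starts <- starts[keep]; ends <- ends[keep]; nonspec <- nonspec[keep]

  missed <- vapply(seq_along(starts), function(p) {
    sum(sites > starts[p] - 1L & sites < ends[p])
  }, integer(1))
  ok <- missed <= max_missed
  starts <- starts[ok]; ends <- ends[ok]
  nonspec <- nonspec[ok]; missed <- missed[ok]

  len <- ends - starts + 1L
  ok <- len >= length_range[1L] & len <= length_range[2L]
  if (any(ok) && (mass_range[1L] > 0 || is.finite(mass_range[2L]))) {
    seqs <- substring(sequence, starts, ends)
    mass <- vapply(seqs, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
    ok <- ok & mass >= mass_range[1L] & mass <= mass_range[2L]
  }
  starts <- starts[ok]; ends <- ends[ok]
  nonspec <- nonspec[ok]; missed <- missed[ok]

  ord <- order(starts, ends, nonspec)
  data.frame(
    sequence = substring(sequence, starts[ord], ends[ord]),
    start = starts[ord], end = ends[ord],
    missed_cleavages = missed[ord], nonspecific_termini = nonspec[ord],
    enzyme = rule$name, stringsAsFactors = FALSE
  )
}
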