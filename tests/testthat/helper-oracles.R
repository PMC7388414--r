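# Shared helpers: an independent brute-force digestion oracle, a random
# sequence generator, and reference-table conveniences.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# independent scan of cleavage positions from the rule definition
oracle_sites <- function(sequence, rule) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  out <- integer(0)
  for (i in seq_len(max(0L, L - 1L))) {
    hit <- if (rule$side == "C") {
      aa[i] %in% rule$targets && !(aa[i + 1] %in% rule$blocked_by_next)
    } else {
      aa[i + 1] %in% rule$targets && !(aa[i] %in% rule$blocked_by_next)
    }
    if (hit) out <- c(out, i)
  }
  out
}

# brute force: every substring, filtered by the specificity predicate
oracle_digest <- function(sequence, rule, max_missed, max_nonspecific) {
  L <- nchar(sequence)
  sites <- oracle_sites(sequence, rule)
  left_ok <- c(0L, sites)
  right_ok <- c(sites, L)
  rows <- list()
  for (a in 1:L) for (b in a:L) {
    nonspec <- 2L - (a - 1L) %in% left_ok - b %in% right_ok
    missed <- sum(sites > a - 1L & sites < b)
    if (nonspec <= max_nonspecific && missed <= max_missed) {
      rows[[length(rows) + 1L]] <- c(a, b, missed, nonspec)
    }
  }
  m <- do.call(rbind, rows)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  colnames(m) <- c("start", "end", "missed", "nonspec")
  m
}

# reference toxins with the modification column parsed into lists
reference_toxins_parsed <- function() {
  tox <- reference_toxins()
  tox$mod_list <- lapply(tox$modifications, function(m) {
    if (is.na(m) || !nzchar(m)) NULL else strsplit(m, ";", fixed = TRUE)[[1]]
  })
  tox
}

theoretical_reference_masses <- function(tox = reference_toxins_parsed()) {
  unname(mapply(function(s, ss, ml) monoisotopic_mass(s, ss, ml),
                tox$mass_sequence, tox$ss_bonds, tox$mod_list))
}
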