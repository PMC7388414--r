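# Native precursor-ion handling: intensity filtering, single-linkage
# clustering of decharged ions, theoretical charge ladders, and mass-based
# toxin validation at ppm tolerance.

.check_ion_table <- function(ions) {
  stopifnot(is.data.frame(ions),
            all(c("mz", "charge", "intensity") %in% names(ions)))
  ions
}

#' Filter precursor ions by intensity
#'
#' Ions with intensity strictly below the threshold are excluded; an ion at
#' exactly the threshold is kept. Rows with negative intensity are dropped
#' with a warning. Input order is preserved.
#'
#' @param ions Data frame with at least `mz`, `charge`, `intensity`.
#' @param min_intensity Intensity threshold; default 5.0e5 (arbitrary
#'   units), the native-peptidomics reporting threshold.
#' @return The retained subset of `ions`.
#' @export
filter_ions <- function(ions, min_intensity = 5.0e5) {
  ions <- .check_ion_table(ions)
  neg <- !is.na(ions$intensity) & ions$intensity < 0
  if (any(neg)) {
    warning(sprintf("dropping %d ion(s) with negative intensity", sum(neg)))
    ions <- ions[!neg, , drop = FALSE]
  }
  ions[!is.na(ions$intensity) & ions$intensity >= min_intensity, ,
       drop = FALSE]
}

#' Cluster precursor ions by neutral mass
#'
#' Decharges every known-charge ion to its neutral mass and single-links
#' ions whose masses fall within a relative tolerance, merging redundant
#' observations of one species across runs and charge states (summing their
#' intensities) instead of discarding them; `mode = "exclude"` instead keeps
#' only the most intense member of each cluster, the discard convention.
#' Ions with unknown charge (`charge == 0`) cannot be decharged and pass
#' through as singleton clusters flagged unclustered.
#'
#' @param ions Data frame with `mz`, `charge`, `intensity` (optionally
#'   `rt`, `run_id`).
#' @param ppm_tol Single-linkage tolerance in ppm.
#' @param mode `"merge"` (default) or `"exclude"`.
#' @return Object of class `ion_clusters`: list with `clusters` (data frame:
#'   `cluster_id`, `neutral_mass`, `n_members`, `total_intensity`, `charges`
#'   comma-separated, `unclustered`) and `members` (`ions` plus `neutral_mass`
#'   and `cluster_id`). Every input ion appears in exactly one cluster.
#' @export
cluster_ions <- function(ions, ppm_tol = 10, mode = c("merge", "exclude")) {
  mode <- match.arg(mode)
  ions <- .check_ion_table(ions)
  n <- nrow(ions)
  if (n == 0L) {
    empty <- data.frame(cluster_id = integer(), neutral_mass = numeric(),
                        n_members = integer(), total_intensity = numeric(),
                        charges = character(), unclustered = logical(),
                        stringsAsFactors = FALSE)
    ions$neutral_mass <- numeric(0)
    ions$cluster_id <- integer(0)
    return(structure(list(clusters = empty, members = ions,
                          ppm_tol = ppm_tol, mode = mode),
                     class = "ion_clusters"))
  }
  ions$neutral_mass <- NA_real_
  known <- !is.na(ions$charge) & ions$charge >= 1L
  if (any(known)) {
    ions$neutral_mass[known] <- mass_from_mz(ions$mz[known],
                                             ions$charge[known])
  }
  cluster_id <- integer(n)
  if (any(known)) {
    ki <- which(known)
    ord <- ki[order(ions$neutral_mass[ki])]
    m <- ions$neutral_mass[ord]
    # single linkage in 1-D: break where the adjacent gap exceeds tolerance
    newc <- c(TRUE, diff(m) / m[-length(m)] * 1e6 > ppm_tol)
    cluster_id[ord] <- cumsum(newc)
  }
  n_known_cl <- if (any(known)) max(cluster_id) else 0L
  cluster_id[!known] <- n_known_cl + seq_len(sum(!known))
  ions$cluster_id <- cluster_id

  agg <- lapply(split(seq_len(n), cluster_id), function(idx) {
    data.frame(
      neutral_mass = mean(ions$neutral_mass[idx]),
      n_members = length(idx),
      total_intensity = sum(ions$intensity[idx]),
      charges = paste(sort(unique(ions$charge[idx])), collapse = ","),
      unclustered = all(!known[idx]),
      stringsAsFactors = FALSE
    )
  })
  clusters <- do.call(rbind, agg)
  clusters <- cbind(cluster_id = as.integer(names(agg)), clusters)
  rownames(clusters) <- NULL
  if (mode == "exclude") {
    keep <- unlist(lapply(split(seq_len(n), cluster_id), function(idx) {
      idx[which.max(ions$intensity[idx])]
    }), use.names = FALSE)
    ions <- ions[sort(keep), , drop = FALSE]
    clusters$n_members <- 1L
    clusters$total_intensity <-
      ions$intensity[match(clusters$cluster_id, ions$cluster_id)]
  }
  structure(list(clusters = clusters, members = ions, ppm_tol = ppm_tol,
                 mode = mode),
            class = "ion_clusters")
}

#' @export
print.ion_clusters <- function(x, ...) {
  cat(sprintf("<ion_clusters> %d ions in %d clusters (%s mode, %g ppm)\n",
              nrow(x$members), nrow(x$clusters), x$mode, x$ppm_tol))
  invisible(x)
}

#' Theoretical m/z charge ladder
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param z_min,z_max Charge range; the default +2 to +9 spans the charge
#'   states expected of intact venom peptides under electrospray.
#' @return Data frame with columns `z` and `mz`, m/z strictly decreasing
#'   in `z`.
#' @export
#' @examples
#' theoretical_ladder(3690.489)
theoretical_ladder <- function(neutral_mass, z_min = 2L, z_max = 9L) {
  if (z_min > z_max || z_min < 1L) stop("invalid charge range", call. = FALSE)
  z <- seq.int(z_min, z_max)
  data.frame(z = z, mz = mz_from_mass(neutral_mass, z))
}

#' Validate toxins against an ion-cluster map
#'
#' A toxin matches a cluster when the relative error between its theoretical
#' neutral mass and the cluster's neutral mass is within `ppm_tol` (ppm is
#' computed against the theoretical mass) and the cluster contains at least
#' one member ion with a known charge inside `[z_min, z_max]`. Validation
#' additionally requires MS/MS-supported sequence evidence unless
#' `require_msms = FALSE`.
#'
#' @param toxins Data frame with columns `id`, `sequence`, `ss_bonds`,
#'   optionally `modifications` (semicolon-separated catalog names) and
#'   `msms_supported` (logical).
#' @param clusters An [cluster_ions()] result.
#' @param ppm_tol Matching tolerance in ppm.
#' @param z_min,z_max Charge states eligible to trigger a match.
#' @param require_msms Require `msms_supported` for validation.
#' @return Data frame with one row per toxin: `toxin_id`,
#'   `theoretical_mass`, `matched_charges` (comma-separated),
#'   `best_ppm_error` (signed, observed relative to theoretical),
#'   `msms_supported`, `validated`.
#' @export
match_toxins <- function(toxins, clusters, ppm_tol = 10, z_min = 2L,
                         z_max = 9L, require_msms = TRUE) {
  stopifnot(inherits(clusters, "ion_clusters"),
            all(c("id", "sequence", "ss_bonds") %in% names(toxins)))
  mods <- if ("modifications" %in% names(toxins)) toxins$modifications
          else rep("", nrow(toxins))
  msms <- if ("msms_supported" %in% names(toxins)) toxins$msms_supported
          else rep(TRUE, nrow(toxins))
  members <- clusters$members
  cl <- clusters$clusters

  out <- lapply(seq_len(nrow(toxins)), function(i) {
    ml <- if (is.na(mods[i]) || !nzchar(mods[i])) NULL
          else strsplit(mods[i], ";", fixed = TRUE)[[1L]]
    theo <- monoisotopic_mass(toxins$sequence[i], toxins$ss_bonds[i], ml)
    ppm <- (cl$neutral_mass - theo) / theo * 1e6
    hit <- !is.na(ppm) & abs(ppm) <= ppm_tol & !cl$unclustered
    # a match must be carried by >= 1 member ion in the eligible charge range
    eligible <- vapply(cl$cluster_id, function(cid) {
      mi <- members$cluster_id == cid & !is.na(members$charge) &
        members$charge >= z_min & members$charge <= z_max
      any(mi)
    }, logical(1))
    hit <- hit & eligible
    zs <- integer(0)
    if (any(hit)) {
      mi <- members$cluster_id %in% cl$cluster_id[hit] &
        !is.na(members$charge) & members$charge >= z_min &
        members$charge <= z_max
      zs <- sort(unique(members$charge[mi]))
    }
    matched <- any(hit)
    best <- if (matched) {
      hp <- ppm[hit]
      hp[which.min(abs(hp))]
    } else NA_real_
    data.frame(
      toxin_id = toxins$id[i], theoretical_mass = theo,
      matched_charges = paste(zs, collapse = ","),
      best_ppm_error = best, msms_supported = isTRUE(msms[i]),
      validated = matched && (isTRUE(msms[i]) || !require_msms),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
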