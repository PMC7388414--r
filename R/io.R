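# File formats and configuration: FASTA and schema-checked TSV I/O, the
# pipeline configuration object, and the umbrella run_pipeline() driver.

#' Read a FASTA file of sequences
#'
#' Order-preserving; sequences are upper-cased with stop characters (`*`)
#' and whitespace stripped; duplicate ids are an error.
#'
#' @param path FASTA file path.
#' @return Named character vector (id to sequence).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(gsub("[*[:space:]]", "", as.character(x)))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(c(paste0(">", names(sequences)[i]), sequences[[i]]), con)
  }
  invisible(path)
}

#' Read a TSV with schema checking
#'
#' Header names must include every schema column; numeric columns are
#' checked cell-wise and non-numeric entries reported with their row
#' number. Blank cells become `NA`. Lines starting with `#` are comments.
#'
#' @param path TSV file path.
#' @param schema Named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`, `"logical"`).
#' @return Data frame with at least the schema columns, typed accordingly.
#' @export
read_tsv_checked <- function(path, schema) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE, na.strings = c("", "NA"))
  missing <- setdiff(names(schema), names(raw))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in names(schema)) {
    if (schema[[col]] %in% c("numeric", "integer")) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(v) & !is.na(raw[[col]]))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                     col, bad[1L], raw[[col]][bad[1L]]), call. = FALSE)
      }
      raw[[col]] <- if (schema[[col]] == "integer") as.integer(v) else v
    } else if (schema[[col]] == "logical") {
      raw[[col]] <- as.logical(raw[[col]])
    }
  }
  raw
}

#' Write a TSV
#'
#' Plain UTF-8 tab-separated output with a header row; the inverse of
#' [read_tsv_checked()] (write-then-read is the identity up to type
#' coercion).
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' All defaults equal the study settings the pipeline is built around:
#' 10 ppm mass tolerance, charge ladder +2..+9, 5.0e5 intensity threshold,
#' at most two missed cleavages and one nonspecific terminus, two-enzyme
#' N-terminal consensus, Hi3 filters of three peptides in two replicates,
#' and strict screening thresholds of 0.8 (antimicrobial) and 0.5
#' (anticancer consensus).
#'
#' @param ppm_tol Mass-matching and clustering tolerance, ppm.
#' @param z_min,z_max Validation charge-ladder range.
#' @param min_intensity Precursor-ion intensity threshold.
#' @param max_missed,max_nonspecific Digest settings.
#' @param min_enzymes Distinct enzymes required for the consensus
#'   N-terminus.
#' @param min_peptides,min_replicates Hi3 identification filters.
#' @param amp_threshold,acp_threshold Screening decision thresholds.
#' @param pka_scale,exclude_cys Charge-model settings.
#' @param redundancy_mode `"merge"` or `"exclude"` redundant ions.
#' @param require_msms Validation requires MS/MS-supported sequence.
#' @param seed Seed recorded in the run manifest.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(ppm_tol = 10, z_min = 2L, z_max = 9L,
                            min_intensity = 5.0e5, max_missed = 2L,
                            max_nonspecific = 1L, min_enzymes = 2L,
                            min_peptides = 3L, min_replicates = 2L,
                            amp_threshold = 0.8, acp_threshold = 0.5,
                            pka_scale = "default", exclude_cys = TRUE,
                            redundancy_mode = "merge", require_msms = TRUE,
                            seed = 1L) {
  stopifnot(ppm_tol > 0, z_min >= 1L, z_max >= z_min, min_intensity >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Hash of a configuration
#'
#' Stable content hash (MD5 of the serialised configuration) echoed into
#' every output file so reruns are traceable to their settings.
#'
#' @param config A [pipeline_config()] (or any serialisable object).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full validation pipeline
#'
#' Executes filter, cluster, coverage/consensus, mass validation,
#' physicochemical profiling, Hi3 quantification and bioactivity screening
#' on whatever inputs are supplied, and optionally writes one TSV per stage
#' plus a YAML run manifest (configuration echo, config hash, seed, row
#' counts).
#'
#' @param inputs Named list. Required: `toxins` (data frame: `id`,
#'   `sequence`, `ss_bonds`; optional `modifications`, `is_crp`) and `ions`
#'   (data frame: `mz`, `charge`, `intensity`). Optional: `parents` (named
#'   character vector of precursor sequences), `evidence` (peptide evidence
#'   in precursor coordinates), `boundaries` (data frame `toxin_id`,
#'   `predicted_start`), `quant` (Hi3 input table), `scores` (screening
#'   score table).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for stage TSVs and the manifest, or
#'   `NULL` to skip writing.
#' @return List of stage results (class `venomtox_run`): `ions_kept`,
#'   `clusters`, `coverage`, `validation`, `physchem`, `quant`,
#'   `screening`, `manifest`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            is.list(inputs), !is.null(inputs$toxins), !is.null(inputs$ions))
  toxins <- inputs$toxins

  ions_kept <- .stage("filter_ions",
                      filter_ions(inputs$ions, config$min_intensity))
  if (!nrow(ions_kept)) {
    warning("no precursor ions survive the intensity filter; ",
            "no toxin can be validated")
  }
  clusters <- .stage("cluster_ions",
                     cluster_ions(ions_kept, config$ppm_tol,
                                  config$redundancy_mode))

  coverage_tab <- NULL
  if (!is.null(inputs$evidence) && !is.null(inputs$parents)) {
    coverage_tab <- .stage("coverage", {
      bnd <- inputs$boundaries
      rows <- lapply(seq_len(nrow(toxins)), function(i) {
        id <- toxins$id[i]
        parent <- inputs$parents[[id]]
        ev <- inputs$evidence[inputs$evidence$parent_id == id, , drop = FALSE]
        cov <- build_coverage(ev, parent, id)
        obs <- consensus_n_terminus(cov, config$min_enzymes)
        span_start <- if (!is.na(obs)) obs else NA_integer_
        full <- if (!is.na(span_start)) {
          is_fully_sequenced(cov, c(span_start,
                                    span_start + nchar(toxins$sequence[i]) - 1L))
        } else list(fully_sequenced = FALSE, first_gap = NA_integer_)
        pred <- if (!is.null(bnd)) {
          b <- bnd$predicted_start[match(id, bnd$toxin_id)]
          if (length(b)) b else NA_integer_
        } else NA_integer_
        cmp <- if (!is.na(pred) && !is.na(obs)) {
          compare_maturation(pred, obs, parent)
        } else data.frame(predicted_start = pred, observed_start = obs,
                          delta_residues = NA_integer_,
                          extension_sequence = NA_character_)
        cbind(data.frame(toxin_id = id,
                         coverage_fraction = mean(cov$depth > 0),
                         fully_sequenced = full$fully_sequenced,
                         first_gap = full$first_gap,
                         stringsAsFactors = FALSE),
              cmp)
      })
      do.call(rbind, rows)
    })
    toxins$msms_supported <- coverage_tab$fully_sequenced[
      match(toxins$id, coverage_tab$toxin_id)]
  }

  validation <- .stage("match_toxins",
                       match_toxins(toxins, clusters, config$ppm_tol,
                                    config$z_min, config$z_max,
                                    config$require_msms))

  model <- charge_model(config$pka_scale, config$exclude_cys)
  physchem <- .stage("physchem", {
    do.call(rbind, lapply(seq_len(nrow(toxins)), function(i) {
      is_crp <- if ("is_crp" %in% names(toxins)) toxins$is_crp[i]
                else toxins$ss_bonds[i] > 0
      m <- if (is_crp) model else charge_model(config$pka_scale, FALSE)
      comp <- aa_composition(toxins$sequence[i], exclude_cys = is_crp)
      data.frame(toxin_id = toxins$id[i],
                 net_charge_ph7.4 = net_charge(toxins$sequence[i], 7.4, m),
                 pI = isoelectric_point(toxins$sequence[i], m),
                 hydrophobic_percent =
                   comp$percent[comp$class == "hydrophobic"],
                 stringsAsFactors = FALSE)
    }))
  })

  quant <- if (!is.null(inputs$quant)) {
    .stage("quantify", quantify_proteins(inputs$quant, config$min_peptides,
                                         config$min_replicates))
  }
  screening <- if (!is.null(inputs$scores)) {
    .stage("screen", screen_toxins(inputs$scores, config$amp_threshold,
                                   config$acp_threshold))
  }

  manifest <- list(
    config = unclass(config), config_hash = config_hash(config),
    n_input_ions = nrow(inputs$ions), n_ions_kept = nrow(ions_kept),
    n_clusters = nrow(clusters$clusters),
    n_toxins = nrow(toxins), n_validated = sum(validation$validated)
  )
  res <- structure(
    list(ions_kept = ions_kept, clusters = clusters,
         coverage = coverage_tab, validation = validation,
         physchem = physchem, quant = quant, screening = screening,
         manifest = manifest),
    class = "venomtox_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(ions_kept, file.path(out_dir, "ions_kept.tsv"))
    write_tsv(clusters$clusters, file.path(out_dir, "clusters.tsv"))
    if (!is.null(coverage_tab)) {
      write_tsv(coverage_tab, file.path(out_dir, "coverage.tsv"))
    }
    write_tsv(validation, file.path(out_dir, "validation.tsv"))
    write_tsv(physchem, file.path(out_dir, "physchem.tsv"))
    if (!is.null(quant)) write_tsv(quant, file.path(out_dir, "quant.tsv"))
    if (!is.null(screening)) {
      write_tsv(screening, file.path(out_dir, "screening.tsv"))
    }
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  res
}

#' @export
print.venomtox_run <- function(x, ...) {
  m <- x$manifest
  cat("<venomtox_run>\n")
  cat(sprintf("  ions: %d in, %d kept, %d clusters\n", m$n_input_ions,
              m$n_ions_kept, m$n_clusters))
  cat(sprintf("  toxins: %d assessed, %d validated\n", m$n_toxins,
              m$n_validated))
  cat(sprintf("  config hash: %s\n", m$config_hash))
  invisible(x)
}
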