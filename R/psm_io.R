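#' @importFrom rlang .data
NULL

design_roles <- c("probe_only", "no_probe_control",
                  "active_competition", "inactive_competition")

#' Roles that anchor a candidate list (probe-labeled samples)
#'
#' A protein can only be "identified" in a probe-only or
#' inactive-competition sample; all other roles serve as exclusion
#' references.
#' @keywords internal
qualifying_roles <- c("probe_only", "inactive_competition")

stop_io <- function(fmt, ..., class) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "competeMS_error"))
}

#' Construct and validate a sample design
#'
#' A sample design maps every mass-spectrometry sample to its run, probe
#' and experimental role. Roles follow the competition layout of
#' probe-based target identification: \code{probe_only} (probe, no
#' pretreatment), \code{inactive_competition} (probe after pretreatment
#' with a biologically inactive analog), \code{active_competition} (probe
#' after pretreatment with the parent compound or an active analog) and
#' \code{no_probe_control} (compound only, no probe). No-probe controls
#' carry probe \code{"NONE"} and are shared by all probes within a run.
#'
#' @param df Data frame with columns \code{sample_id}, \code{run_id},
#'   \code{probe}, \code{role}, and optionally \code{treatment_label} and
#'   \code{concentration_uM}.
#' @return A validated \code{sample_design} tibble.
#' @export
sample_design <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("sample_id", "run_id", "probe", "role")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_io("design is missing column(s): %s", paste(missing, collapse = ", "),
            class = "competeMS_design_error")
  }
  if (nrow(df) == 0) {
    stop_io("design contains no samples", class = "competeMS_design_error")
  }
  if (!"treatment_label" %in% names(df)) df$treatment_label <- NA_character_
  if (!"concentration_uM" %in% names(df)) df$concentration_uM <- NA_real_
  df$sample_id <- as.character(df$sample_id)
  df$probe <- as.character(df$probe)
  df$role <- as.character(df$role)
  df$run_id <- as.integer(df$run_id)
  df$concentration_uM <- as.numeric(df$concentration_uM)

  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    stop_io("duplicate sample_id in design: %s",
            paste(unique(dup), collapse = ", "),
            class = "competeMS_design_error")
  }
  bad_role <- setdiff(unique(df$role), design_roles)
  if (length(bad_role) > 0) {
    stop_io("unknown role token(s): %s (must be one of %s)",
            paste(bad_role, collapse = ", "),
            paste(design_roles, collapse = ", "),
            class = "competeMS_vocabulary_error")
  }
  if (any(is.na(df$run_id)) || any(df$run_id < 1L)) {
    stop_io("run_id must be an integer >= 1", class = "competeMS_design_error")
  }
  if (any(!is.na(df$concentration_uM) & df$concentration_uM < 0)) {
    stop_io("concentration_uM must be nonnegative",
            class = "competeMS_design_error")
  }
  needs_probe <- df$role %in% c("probe_only", "active_competition",
                                "inactive_competition")
  if (any(needs_probe & df$probe == "NONE")) {
    bad <- df$sample_id[needs_probe & df$probe == "NONE"]
    stop_io("sample(s) %s carry a probe-dependent role but probe NONE",
            paste(bad, collapse = ", "), class = "competeMS_design_error")
  }
  if (any(!needs_probe & df$probe != "NONE")) {
    bad <- df$sample_id[!needs_probe & df$probe != "NONE"]
    stop_io("no_probe_control sample(s) %s must carry probe NONE",
            paste(bad, collapse = ", "), class = "competeMS_design_error")
  }

  # each (run, probe) pair with any qualifying sample needs exactly one
  # probe-only anchor in that run
  qual <- df[df$role %in% qualifying_roles, , drop = FALSE]
  for (key in unique(paste(qual$run_id, qual$probe, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    run <- as.integer(parts[1]); probe <- parts[2]
    n_po <- sum(df$run_id == run & df$probe == probe &
                  df$role == "probe_only")
    if (n_po != 1L) {
      stop_io("run %d, probe %s: expected exactly one probe_only sample, found %d",
              run, probe, n_po, class = "competeMS_design_error")
    }
  }
  # every run with a probe-only sample needs at least one exclusion-side sample
  for (run in unique(df$run_id[df$role == "probe_only"])) {
    in_run <- df[df$run_id == run, , drop = FALSE]
    if (!any(in_run$role %in% c("no_probe_control", "active_competition"))) {
      stop_io("run %d has probe_only sample(s) but no exclusion-side sample (no_probe_control or active_competition)",
              run, class = "competeMS_design_error")
    }
  }
  structure(df, class = c("sample_design", class(tibble::tibble())))
}

#' Read a sample design from a tab-separated file
#'
#' Expects one header line and one row per sample with columns
#' \code{sample_id}, \code{run_id}, \code{probe}, \code{role} and
#' optionally \code{treatment_label}, \code{concentration_uM}.
#'
#' @param path Path to the design file.
#' @return A validated \code{\link{sample_design}}.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    stop_io("design file not found: %s", path, class = "competeMS_io_error")
  }
  df <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) {
      stop_io("cannot parse design file %s: %s", path, conditionMessage(e),
              class = "competeMS_parse_error")
    })
  if (nrow(df) == 0) {
    stop_io("design file %s is empty", path, class = "competeMS_design_error")
  }
  sample_design(df)
}

#' Write a sample design to a tab-separated file
#' @param design A \code{\link{sample_design}}.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(tibble::as_tibble(design), path, progress = FALSE)
  invisible(path)
}

protein_table_cols <- c("accession", "gene_symbol", "psm_count",
                        "n_peptides", "n_unique_peptides")

validate_evidence <- function(df, sample_id, file = "<in-memory>") {
  df <- tibble::as_tibble(df)
  if (!"gene_symbol" %in% names(df)) df$gene_symbol <- NA_character_
  missing <- setdiff(setdiff(protein_table_cols, "gene_symbol"), names(df))
  if (length(missing) > 0) {
    stop_io("%s (sample %s): missing column(s) %s", file, sample_id,
            paste(missing, collapse = ", "), class = "competeMS_parse_error")
  }
  df <- df[protein_table_cols]
  df$accession <- as.character(df$accession)
  df$gene_symbol <- as.character(df$gene_symbol)
  for (col in c("psm_count", "n_peptides", "n_unique_peptides")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop_io("%s (sample %s), line %d: field %s is not an integer",
              file, sample_id, bad[1] + 1L, col,
              class = "competeMS_parse_error")
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      stop_io("%s (sample %s), line %d: field %s is negative",
              file, sample_id, neg[1] + 1L, col,
              class = "competeMS_parse_error")
    }
    df[[col]] <- v
  }
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup) > 0) {
    stop_io("%s: duplicate accession %s within sample %s",
            file, unique(dup)[1], sample_id,
            class = "competeMS_evidence_error")
  }
  bad <- which(df$n_unique_peptides > df$n_peptides)
  if (length(bad) > 0) {
    stop_io("%s (sample %s), line %d: field n_unique_peptides exceeds n_peptides for %s",
            file, sample_id, bad[1] + 1L, df$accession[bad[1]],
            class = "competeMS_evidence_error")
  }
  bad <- which(df$n_peptides > df$psm_count)
  if (length(bad) > 0) {
    stop_io("%s (sample %s), line %d: field n_peptides exceeds psm_count for %s",
            file, sample_id, bad[1] + 1L, df$accession[bad[1]],
            class = "competeMS_evidence_error")
  }
  bad <- which(df$psm_count == 0L)
  if (length(bad) > 0) {
    stop_io("%s (sample %s), line %d: zero-PSM row for %s (absence is encoded by omission)",
            file, sample_id, bad[1] + 1L, df$accession[bad[1]],
            class = "competeMS_evidence_error")
  }
  df
}

#' Bundle per-sample protein evidence with its design
#'
#' @param design A \code{\link{sample_design}}.
#' @param tables Named list (names are sample ids) of protein evidence
#'   tables with columns \code{accession}, optional \code{gene_symbol},
#'   \code{psm_count}, \code{n_peptides}, \code{n_unique_peptides}. A
#'   protein absent from a sample is simply omitted from that sample's
#'   table; zero-PSM rows are rejected.
#' @return A \code{run_tables} object.
#' @export
run_tables <- function(design, tables) {
  design <- if (inherits(design, "sample_design")) design else sample_design(design)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop_io("tables must be a named list keyed by sample_id",
            class = "competeMS_unknown_sample_error")
  }
  unknown <- setdiff(names(tables), design$sample_id)
  if (length(unknown) > 0) {
    stop_io("sample id(s) not in design: %s", paste(unknown, collapse = ", "),
            class = "competeMS_unknown_sample_error")
  }
  tables <- lapply(stats::setNames(names(tables), names(tables)), function(sid) {
    validate_evidence(tables[[sid]], sid)
  })
  structure(list(design = design, tables = tables), class = "run_tables")
}

#' Read per-sample protein identification tables
#'
#' Each file is a tab-separated table with one header line and columns
#' \code{accession}, \code{gene_symbol} (optional), \code{psm_count},
#' \code{n_peptides}, \code{n_unique_peptides} -- the shape of a search
#' engine protein export.
#'
#' @param paths Character vector of file paths. If named, names are the
#'   sample ids; otherwise the file base name (without extension) is used.
#' @param design A \code{\link{sample_design}} the samples must belong to.
#' @return A \code{\link{run_tables}} object.
#' @export
read_run_tables <- function(paths, design) {
  ids <- names(paths)
  if (is.null(ids)) {
    ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  tables <- stats::setNames(vector("list", length(paths)), ids)
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) {
      stop_io("protein table not found: %s", paths[i],
              class = "competeMS_io_error")
    }
    df <- tryCatch(
      readr::read_tsv(paths[i], show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character())),
      error = function(e) {
        stop_io("cannot parse %s: %s", paths[i], conditionMessage(e),
                class = "competeMS_parse_error")
      })
    tables[[i]] <- validate_evidence(df, ids[i], file = paths[i])
  }
  run_tables(design, tables)
}

#' Write per-sample protein tables (one file per sample)
#' @param rt A \code{\link{run_tables}} object.
#' @param dir Output directory; created if needed.
#' @return Named character vector of file paths.
#' @export
write_run_tables <- function(rt, dir) {
  stopifnot(inherits(rt, "run_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(
    file.path(dir, paste0(names(rt$tables), ".tsv")), names(rt$tables))
  for (sid in names(rt$tables)) {
    readr::write_tsv(rt$tables[[sid]], paths[[sid]], progress = FALSE)
  }
  invisible(paths)
}

#' Write a candidate set as a deterministic tab-separated table
#'
#' Rows are ordered by rank; repeated calls on the same input are
#' byte-identical. An empty candidate set yields a header-only file.
#'
#' @param candidate_set A \code{candidate_set} from
#'   \code{\link{consensus_candidates}}.
#' @param path Output path.
#' @export
write_candidates <- function(candidate_set, path) {
  stopifnot(inherits(candidate_set, "candidate_set"))
  cols <- c("accession", "gene_symbol", "hit_count", "hit_pattern",
            "total_psm", "rank")
  df <- candidate_set$candidates[order(candidate_set$candidates$rank), cols]
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a one-accession-per-line set export
#' @param x A \code{candidate_set} or character vector of accessions.
#' @param path Output path.
#' @export
write_accessions <- function(x, path) {
  acc <- accessions_of(x)
  writeLines(sort(acc), path)
  invisible(path)
}

#' Read a one-accession-per-line list
#' @param path Input path.
#' @return Character vector of accessions (blank lines dropped).
#' @export
read_accessions <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

accessions_of <- function(x) {
  if (inherits(x, "candidate_set")) x$candidates$accession
  else if (is.character(x)) x
  else stop_io("expected a candidate_set or character vector",
               class = "competeMS_type_error")
}

#' @export
print.run_tables <- function(x, ...) {
  cat(sprintf("run_tables: %d samples over %d run(s), %d probe(s)\n",
              length(x$tables), length(unique(x$design$run_id)),
              length(setdiff(unique(x$design$probe), "NONE"))))
  n <- vapply(x$tables, nrow, integer(1))
  cat(sprintf("  proteins per sample: median %d (range %d-%d)\n",
              as.integer(stats::median(n)), min(n), max(n)))
  invisible(x)
}
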