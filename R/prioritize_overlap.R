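add_rank <- function(candidates) {
  ord <- order(-candidates$total_psm, -candidates$n_unique_max,
               candidates$accession)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  candidates
}

#' Rank candidates by spectral counts
#'
#' Candidates are prioritized by descending summed PSM count over the
#' qualifying slots where they were identified; ties are broken by the
#' maximum unique-peptide count (descending), then by accession
#' (ascending), so the order is total and stable. Rank is 1-based.
#'
#' @param candidate_set A \code{candidate_set} from
#'   \code{\link{consensus_candidates}}.
#' @return Tibble of candidates in rank order with a \code{rank} column.
#' @export
rank_candidates <- function(candidate_set) {
  stopifnot(inherits(candidate_set, "candidate_set"))
  add_rank(candidate_set$candidates)
}

#' Intersect the candidate sets of two probes
#'
#' Structurally distinct probes of the same parent compound capture
#' overlapping but non-identical target profiles; the shared set is the
#' high-confidence core. Accession is the intersection key.
#'
#' @param candidates_a,candidates_b \code{candidate_set} objects or
#'   character vectors of accessions.
#' @param probe_a,probe_b Probe labels, required when the inputs are bare
#'   accession vectors.
#' @return A \code{venn_summary}: probe labels, \code{only_a},
#'   \code{only_b} and \code{shared} accession sets with counts.
#' @export
intersect_probes <- function(candidates_a, candidates_b,
                             probe_a = NULL, probe_b = NULL) {
  a <- unique(accessions_of(candidates_a))
  b <- unique(accessions_of(candidates_b))
  if (is.null(probe_a)) {
    probe_a <- if (inherits(candidates_a, "candidate_set"))
      candidates_a$probe else "probe_a"
  }
  if (is.null(probe_b)) {
    probe_b <- if (inherits(candidates_b, "candidate_set"))
      candidates_b$probe else "probe_b"
  }
  if (identical(probe_a, probe_b)) {
    rlang::warn(sprintf("self-intersection: both inputs carry probe %s", probe_a))
  }
  shared <- sort(intersect(a, b))
  structure(list(probe_a = probe_a, probe_b = probe_b,
                 only_a = sort(setdiff(a, b)), only_b = sort(setdiff(b, a)),
                 shared = shared,
                 n_a = length(a), n_b = length(b), n_shared = length(shared)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("candidate overlap: %s (%d) vs %s (%d), %d shared\n",
              x$probe_a, x$n_a, x$probe_b, x$n_b, x$n_shared))
  if (x$n_shared > 0) cat("  shared:", paste(x$shared, collapse = ", "), "\n")
  invisible(x)
}

#' Write a deterministic candidate/overlap report
#'
#' Emits, under \code{dir}: one ranked candidate table per probe
#' (\code{candidates_<probe>.tsv}), one accession-per-line set export per
#' probe, an overlap table (\code{venn.tsv}) and a human-readable
#' \code{summary.txt}. Repeated invocation on identical inputs produces
#' byte-identical files.
#'
#' @param candidate_sets List of \code{candidate_set} objects.
#' @param venn A \code{venn_summary} from \code{\link{intersect_probes}},
#'   or \code{NULL}.
#' @param dir Output directory; created if needed.
#' @param top_k Number of top-ranked candidates echoed in the summary.
#' @return Invisibly, the paths written.
#' @export
report <- function(candidate_sets, venn = NULL, dir, top_k = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  lines <- character(0)
  for (cs in candidate_sets) {
    stopifnot(inherits(cs, "candidate_set"))
    p <- file.path(dir, sprintf("candidates_%s.tsv", cs$probe))
    write_candidates(cs, p)
    pl <- file.path(dir, sprintf("accessions_%s.txt", cs$probe))
    write_accessions(cs, pl)
    paths <- c(paths, p, pl)
    lines <- c(lines, sprintf("probe %s: %d candidate(s)", cs$probe,
                              nrow(cs$candidates)))
    top <- utils::head(cs$candidates, top_k)
    if (nrow(top) > 0) {
      lines <- c(lines, sprintf("  %d. %s (%s) total_psm=%d hits=%d",
                                top$rank, top$accession,
                                ifelse(is.na(top$gene_symbol), "-",
                                       top$gene_symbol),
                                top$total_psm, top$hit_count))
    }
  }
  if (!is.null(venn)) {
    stopifnot(inherits(venn, "venn_summary"))
    vt <- tibble::tibble(
      set = c(paste0("only_", venn$probe_a), "shared",
              paste0("only_", venn$probe_b)),
      n = c(length(venn$only_a), venn$n_shared, length(venn$only_b)),
      accessions = c(paste(venn$only_a, collapse = ";"),
                     paste(venn$shared, collapse = ";"),
                     paste(venn$only_b, collapse = ";")))
    vp <- file.path(dir, "venn.tsv")
    readr::write_tsv(vt, vp, progress = FALSE)
    paths <- c(paths, vp)
    lines <- c(lines,
               sprintf("overlap: %s %d / %s %d / shared %d",
                       venn$probe_a, venn$n_a, venn$probe_b, venn$n_b,
                       venn$n_shared))
  }
  sp <- file.path(dir, "summary.txt")
  writeLines(lines, sp)
  paths <- c(paths, sp)
  invisible(paths)
}
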