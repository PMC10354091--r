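#' Filter parameters for competitive target identification
#'
#' Defaults encode the standard competitive chemoproteomic filter:
#' proteins are retained per sample when supported by at least two
#' peptides and one unique peptide, excluded when any exclusion sample in
#' the same run carries more than 0.25-fold the PSM count of the
#' probe-labeled sample, and called candidates when identified in at
#' least 4 of the 6 qualifying samples across three runs.
#'
#' @param ratio_threshold Exclusion ratio; a protein is excluded from a
#'   qualifying sample when any exclusion-sample PSM count exceeds
#'   \code{ratio_threshold} times the qualifying-sample PSM count
#'   (strictly greater; a ratio exactly at the threshold passes).
#' @param min_peptides Minimum peptide count for per-sample retention.
#' @param min_unique Minimum unique-peptide count for per-sample retention.
#' @param min_hits Minimum number of qualifying samples a candidate must
#'   be identified in.
#' @param expected_qualifying_samples Slot count the design is expected
#'   to provide (6 in the canonical 3-run, probe-only + inactive-analog
#'   layout); a differing actual slot count raises a warning.
#' @return A \code{filter_params} list.
#' @export
filter_params <- function(ratio_threshold = 0.25, min_peptides = 2L,
                          min_unique = 1L, min_hits = 4L,
                          expected_qualifying_samples = 6L) {
  stopifnot(is.numeric(ratio_threshold), length(ratio_threshold) == 1,
            ratio_threshold >= 0)
  min_hits <- as.integer(min_hits)
  expected_qualifying_samples <- as.integer(expected_qualifying_samples)
  if (min_hits < 1L || min_hits > expected_qualifying_samples) {
    rlang::abort("min_hits must satisfy 1 <= min_hits <= expected_qualifying_samples",
                 class = "competeMS_config_error")
  }
  structure(list(ratio_threshold = ratio_threshold,
                 min_peptides = as.integer(min_peptides),
                 min_unique = as.integer(min_unique),
                 min_hits = min_hits,
                 expected_qualifying_samples = expected_qualifying_samples),
            class = "filter_params")
}

#' Per-sample evidence gate
#'
#' A protein identification is retained in a sample when it has at least
#' \code{min_peptides} peptides and \code{min_unique} unique peptides.
#'
#' @param evidence Data frame with columns \code{n_peptides} and
#'   \code{n_unique_peptides} (a protein evidence table or any subset).
#' @param params A \code{\link{filter_params}}.
#' @return Logical vector, one element per row of \code{evidence}.
#' @export
evidence_pass <- function(evidence, params = filter_params()) {
  evidence$n_peptides >= params$min_peptides &
    evidence$n_unique_peptides >= params$min_unique
}

#' Competition ratio of an exclusion sample against a probe-labeled sample
#'
#' @param control_psm PSM count(s) in the exclusion (control/competition)
#'   sample; 0 when the protein is absent there.
#' @param reference_psm PSM count(s) in the probe-labeled qualifying
#'   sample.
#' @return \code{control_psm / reference_psm}, or \code{NA} when the
#'   reference count is 0 (the ratio is undefined; such proteins are
#'   simply not identified in the qualifying sample, so undefined ratios
#'   never enter the decision path).
#' @export
competition_ratio <- function(control_psm, reference_psm) {
  stopifnot(all(control_psm >= 0), all(reference_psm >= 0))
  ifelse(reference_psm > 0, control_psm / reference_psm, NA_real_)
}

#' Per-sample identification under competition-based exclusion
#'
#' A protein is identified in a qualifying (probe-labeled) sample when
#' (a) it is present there and passes the evidence gate, and (b) for
#' every exclusion sample of the same run its competition ratio is at or
#' below the threshold. A protein absent from an exclusion sample
#' contributes ratio 0.
#'
#' @param accessions Character vector of accessions to evaluate.
#' @param qualifying Protein evidence table of the qualifying sample.
#' @param exclusions List of protein evidence tables, one per exclusion
#'   sample in the same run (no-probe controls and active-competition
#'   samples).
#' @param params A \code{\link{filter_params}}.
#' @return Logical vector parallel to \code{accessions}.
#' @export
identified_in_sample <- function(accessions, qualifying, exclusions,
                                 params = filter_params()) {
  idx <- match(accessions, qualifying$accession)
  present <- !is.na(idx)
  ok <- present
  ok[present] <- evidence_pass(qualifying[idx[present], , drop = FALSE], params)
  ref_psm <- ifelse(present, qualifying$psm_count[idx], 0L)
  for (excl in exclusions) {
    e_idx <- match(accessions, excl$accession)
    e_psm <- ifelse(is.na(e_idx), 0L, excl$psm_count[e_idx])
    ratio <- competition_ratio(e_psm, ref_psm)
    ok <- ok & !is.na(ratio) & ratio <= params$ratio_threshold
    # absent-from-qualifying rows already FALSE via `present`
    ok[!present] <- FALSE
  }
  ok
}

#' Enumerate the qualifying slots of a probe across runs
#'
#' One slot per probe-labeled sample eligible to contribute an
#' identification: the probe-only sample and any inactive-competition
#' samples of that probe, in each run. Slots are ordered by run, then
#' probe_only before inactive_competition, then sample id.
#'
#' @param design A \code{\link{sample_design}}.
#' @param probe Probe token.
#' @return Tibble with columns \code{run_id}, \code{role},
#'   \code{sample_id} in slot order.
#' @export
qualifying_slots <- function(design, probe) {
  q <- design[design$probe == probe & design$role %in% qualifying_roles, ,
              drop = FALSE]
  role_order <- match(q$role, qualifying_roles)
  q <- q[order(q$run_id, role_order, q$sample_id), , drop = FALSE]
  tibble::tibble(run_id = q$run_id, role = q$role, sample_id = q$sample_id)
}

exclusion_samples <- function(design, probe, run) {
  design$sample_id[design$run_id == run &
                     (design$role == "no_probe_control" |
                        (design$role == "active_competition" &
                           design$probe == probe))]
}

#' Cross-run consensus candidate targets of one probe
#'
#' Applies \code{\link{identified_in_sample}} over every qualifying slot
#' of the probe across runs and retains proteins identified in at least
#' \code{min_hits} slots. The hit pattern records the per-slot decisions
#' in slot order; \code{total_psm} sums the qualifying-sample PSM counts
#' over the slots where the protein was identified, and
#' \code{n_unique_max} is the maximum unique-peptide count over those
#' slots (both are used for prioritization).
#'
#' @param rt A \code{\link{run_tables}} object.
#' @param probe Probe token to build the candidate list for.
#' @param params A \code{\link{filter_params}}.
#' @param audit If \code{TRUE}, attach a per-(protein, slot, exclusion
#'   sample) table of every ratio and gate decision.
#' @return A \code{candidate_set}: list with elements \code{probe},
#'   \code{candidates} (ranked tibble), \code{evaluated} (all assessed
#'   accessions with hit counts), \code{slots}, \code{params} and
#'   optionally \code{audit}.
#' @export
consensus_candidates <- function(rt, probe, params = filter_params(),
                                 audit = FALSE) {
  stopifnot(inherits(rt, "run_tables"))
  design <- rt$design
  slots <- qualifying_slots(design, probe)
  if (nrow(slots) == 0) {
    rlang::abort(sprintf("no qualifying samples for probe %s in the design", probe),
                 class = "competeMS_design_error")
  }
  missing_tab <- setdiff(slots$sample_id, names(rt$tables))
  if (length(missing_tab) > 0) {
    rlang::abort(sprintf("qualifying sample(s) missing from run tables: %s",
                         paste(missing_tab, collapse = ", ")),
                 class = "competeMS_design_error")
  }
  if (nrow(slots) < params$min_hits) {
    rlang::abort(sprintf(
      "design provides %d qualifying slot(s) for probe %s but min_hits is %d: the candidate set would be provably empty",
      nrow(slots), probe, params$min_hits), class = "competeMS_config_error")
  }
  if (nrow(slots) != params$expected_qualifying_samples) {
    rlang::warn(sprintf("probe %s has %d qualifying slots (expected %d)",
                        probe, nrow(slots),
                        params$expected_qualifying_samples))
  }

  all_acc <- sort(unique(unlist(
    lapply(slots$sample_id, function(s) rt$tables[[s]]$accession),
    use.names = FALSE)))
  n <- length(all_acc)
  hit <- matrix(FALSE, nrow = n, ncol = nrow(slots))
  psm_in_slot <- matrix(0L, nrow = n, ncol = nrow(slots))
  uniq_in_slot <- matrix(0L, nrow = n, ncol = nrow(slots))
  audit_rows <- list()

  for (j in seq_len(nrow(slots))) {
    q_tab <- rt$tables[[slots$sample_id[j]]]
    excl_ids <- exclusion_samples(design, probe, slots$run_id[j])
    excl_ids <- intersect(excl_ids, names(rt$tables))
    if (length(excl_ids) == 0) {
      rlang::warn(sprintf(
        "run %d has no exclusion sample with data for probe %s; no competition applied in slot %s",
        slots$run_id[j], probe, slots$sample_id[j]))
    }
    excl_tabs <- rt$tables[excl_ids]
    hit[, j] <- identified_in_sample(all_acc, q_tab, excl_tabs, params)
    idx <- match(all_acc, q_tab$accession)
    psm_in_slot[, j] <- ifelse(is.na(idx), 0L, q_tab$psm_count[idx])
    uniq_in_slot[, j] <- ifelse(is.na(idx), 0L, q_tab$n_unique_peptides[idx])
    if (audit) {
      present <- !is.na(idx)
      gate <- rep(FALSE, n)
      gate[present] <- evidence_pass(q_tab[idx[present], , drop = FALSE], params)
      base <- tibble::tibble(
        accession = all_acc,
        run_id = slots$run_id[j],
        qualifying_sample = slots$sample_id[j],
        role = slots$role[j],
        psm_count = psm_in_slot[, j],
        n_peptides = ifelse(is.na(idx), 0L, q_tab$n_peptides[idx]),
        n_unique_peptides = uniq_in_slot[, j],
        evidence_pass = gate)
      if (length(excl_tabs) == 0) {
        base$exclusion_sample <- NA_character_
        base$exclusion_psm <- NA_integer_
        base$ratio <- NA_real_
        base$excluded <- FALSE
        base$identified <- hit[, j]
        audit_rows[[length(audit_rows) + 1L]] <- base
      } else {
        for (eid in names(excl_tabs)) {
          e_idx <- match(all_acc, excl_tabs[[eid]]$accession)
          e_psm <- ifelse(is.na(e_idx), 0L, excl_tabs[[eid]]$psm_count[e_idx])
          ratio <- competition_ratio(e_psm, psm_in_slot[, j])
          row <- base
          row$exclusion_sample <- eid
          row$exclusion_psm <- e_psm
          row$ratio <- ratio
          row$excluded <- !is.na(ratio) & ratio > params$ratio_threshold
          row$identified <- hit[, j]
          audit_rows[[length(audit_rows) + 1L]] <- row
        }
      }
    }
  }

  hit_count <- as.integer(rowSums(hit))
  total_psm <- as.integer(rowSums(psm_in_slot * hit))
  n_unique_max <- apply(uniq_in_slot * hit, 1L, max)
  pattern <- apply(hit, 1L, function(r) paste(as.integer(r), collapse = ""))
  gene <- gene_symbol_lookup(rt, all_acc)

  evaluated <- tibble::tibble(
    accession = all_acc, gene_symbol = gene,
    hit_count = hit_count, hit_pattern = pattern,
    total_psm = total_psm, n_unique_max = as.integer(n_unique_max))
  candidates <- evaluated[evaluated$hit_count >= params$min_hits, ,
                          drop = FALSE]
  candidates <- add_rank(candidates)

  out <- list(probe = probe, candidates = candidates, evaluated = evaluated,
              slots = slots, params = params)
  if (audit) out$audit <- dplyr::bind_rows(audit_rows)
  structure(out, class = "candidate_set")
}

gene_symbol_lookup <- function(rt, accessions) {
  all_ev <- dplyr::bind_rows(rt$tables)
  all_ev <- all_ev[!is.na(all_ev$gene_symbol), c("accession", "gene_symbol")]
  all_ev <- all_ev[!duplicated(all_ev$accession), , drop = FALSE]
  all_ev$gene_symbol[match(accessions, all_ev$accession)]
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set for probe %s: %d candidate(s) of %d evaluated proteins\n",
              x$probe, nrow(x$candidates), nrow(x$evaluated)))
  cat(sprintf("  filter: ratio > %.3g excludes; >= %d peptides, >= %d unique; >= %d of %d slots\n",
              x$params$ratio_threshold, x$params$min_peptides,
              x$params$min_unique, x$params$min_hits, nrow(x$slots)))
  if (nrow(x$candidates) > 0) {
    print(utils::head(x$candidates, 10))
  }
  invisible(x)
}
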