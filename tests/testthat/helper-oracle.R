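# Brute-force oracle: a literal, loop-based enumeration of the filter
# rules, kept independent of the package implementation. For every
# protein it walks every qualifying sample and every exclusion sample
# with explicit per-row lookups.

oracle_candidates <- function(rt, probe, params = filter_params()) {
  design <- rt$design
  qual <- design[design$probe == probe &
                   design$role %in% c("probe_only", "inactive_competition"), ]
  accs <- character(0)
  for (sid in qual$sample_id) accs <- union(accs, rt$tables[[sid]]$accession)
  out <- character(0)
  for (acc in accs) {
    hits <- 0L
    for (i in seq_len(nrow(qual))) {
      sid <- qual$sample_id[i]
      run <- qual$run_id[i]
      tab <- rt$tables[[sid]]
      row <- tab[tab$accession == acc, ]
      identified <- FALSE
      if (nrow(row) == 1 &&
          row$n_peptides >= params$min_peptides &&
          row$n_unique_peptides >= params$min_unique) {
        identified <- TRUE
        excl_ids <- design$sample_id[
          design$run_id == run &
            (design$role == "no_probe_control" |
               (design$role == "active_competition" & design$probe == probe))]
        for (eid in intersect(excl_ids, names(rt$tables))) {
          etab <- rt$tables[[eid]]
          erow <- etab[etab$accession == acc, ]
          e_psm <- if (nrow(erow) == 1) erow$psm_count else 0L
          if (e_psm / row$psm_count > params$ratio_threshold) {
            identified <- FALSE
          }
        }
      }
      if (identified) hits <- hits + 1L
    }
    if (hits >= params$min_hits) out <- c(out, acc)
  }
  sort(out)
}
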