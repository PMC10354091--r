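# In-memory fixtures: a minimal one-probe design and small hand-built
# evidence tables used across tests.

ev <- function(accession, psm, pep, uniq, gene = NA_character_) {
  tibble::tibble(accession = accession, gene_symbol = gene,
                 psm_count = as.integer(psm), n_peptides = as.integer(pep),
                 n_unique_peptides = as.integer(uniq))
}

# one probe, n_runs runs, per run: probe_only + inactive_competition
# qualifying slots, one no_probe_control and one active_competition
small_design <- function(n_runs = 3, probe = "A") {
  rows <- lapply(seq_len(n_runs), function(r) {
    tibble::tibble(
      sample_id = sprintf("R%d_%s", r, c("probe", "inact", "ctrl", "comp")),
      run_id = r, probe = c(probe, probe, "NONE", probe),
      role = c("probe_only", "inactive_competition", "no_probe_control",
               "active_competition"))
  })
  sample_design(dplyr::bind_rows(rows))
}

# The 5-protein toy: TGT passes every slot; BKG is excluded by ratio 0.5
# in the no-probe control; LOWEV never passes the peptide gate; TWORUN
# appears in 2 slots only (probe-only of runs 1-2); NONSPEC survives
# competition in the active sample at ratio 0.9 and is excluded.
toy_tables <- function(design = small_design()) {
  base_qual <- dplyr::bind_rows(
    ev("TGT", 10, 4, 2), ev("BKG", 10, 4, 2), ev("LOWEV", 8, 1, 1),
    ev("NONSPEC", 10, 5, 3))
  with_tworun <- dplyr::bind_rows(base_qual, ev("TWORUN", 6, 3, 2))
  mk_excl <- dplyr::bind_rows(
    ev("BKG", 5, 3, 1))           # ratio 0.5 for BKG, 0 for the others
  mk_comp <- dplyr::bind_rows(
    ev("NONSPEC", 9, 5, 3))       # ratio 0.9: not competed by the compound
  tabs <- list()
  for (r in 1:3) {
    tabs[[sprintf("R%d_probe", r)]] <- if (r <= 2) with_tworun else base_qual
    tabs[[sprintf("R%d_inact", r)]] <- base_qual
    tabs[[sprintf("R%d_ctrl", r)]] <- mk_excl
    tabs[[sprintf("R%d_comp", r)]] <- mk_comp
  }
  run_tables(design, tabs)
}

# random small experiment, independent of the package's generator, for
# property and oracle-equivalence tests
random_experiment <- function(seed, n_proteins = 30, n_runs = 3,
                              p_present = 0.6) {
  withr::with_seed(seed, {
    design <- small_design(n_runs)
    acc <- sprintf("P%03d", seq_len(n_proteins))
    tabs <- lapply(stats::setNames(design$sample_id, design$sample_id),
                   function(sid) {
      keep <- stats::runif(n_proteins) < p_present
      psm <- 1L + stats::rpois(sum(keep), 6)
      pep <- pmin(psm, 1L + stats::rpois(sum(keep), 2))
      uniq <- vapply(pep, function(k) stats::rbinom(1, k, 0.7), integer(1))
      ev(acc[keep], psm, pep, uniq)
    })
    run_tables(design, tabs)
  })
}
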