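test_that("evidence gate retains two-peptide, one-unique identifications and boundary cases", {
  p <- filter_params()
  expect_true(evidence_pass(ev("X", 5, 2, 1), p))
  expect_false(evidence_pass(ev("X", 5, 1, 1), p))
  expect_false(evidence_pass(ev("X", 5, 3, 0), p))
  # vectorized over rows
  tab <- dplyr::bind_rows(ev("A", 9, 4, 2), ev("B", 9, 1, 0))
  expect_equal(evidence_pass(tab, p), c(TRUE, FALSE))
})

test_that("competition ratio is control over reference, undefined for a zero reference", {
  expect_equal(competition_ratio(5, 10), 0.5)
  expect_equal(competition_ratio(0, 10), 0)
  expect_true(is.na(competition_ratio(3, 0)))
  expect_equal(competition_ratio(c(5, 0, 3), c(10, 10, 0)),
               c(0.5, 0, NA_real_))
})

test_that("per-sample identification combines the evidence gate with all-exclusion competition", {
  p <- filter_params()
  qual <- dplyr::bind_rows(ev("T1", 20, 5, 3), ev("T2", 10, 5, 3),
                           ev("T3", 8, 1, 1))
  ctrl <- dplyr::bind_rows(ev("T1", 2, 2, 1), ev("T2", 5, 3, 1))
  comp <- dplyr::bind_rows(ev("T2", 1, 1, 1))

  # max ratio 0.10 across exclusion samples: identified
  expect_true(identified_in_sample("T1", qual, list(ctrl, comp), p))
  # ratio 0.50 in the no-probe control: excluded
  expect_false(identified_in_sample("T2", qual, list(ctrl, comp), p))
  # evidence gate fails regardless of controls
  expect_false(identified_in_sample("T3", qual, list(), p))
  # absent from the qualifying sample: not identified
  expect_false(identified_in_sample("T9", qual, list(ctrl), p))
  # ratio exactly at the threshold passes (exclusion is strictly >)
  qual2 <- ev("T1", 8, 4, 2); ctrl2 <- ev("T1", 2, 2, 1)
  expect_true(identified_in_sample("T1", qual2, list(ctrl2), p))
  ctrl3 <- ev("T1", 3, 2, 1)   # 3/8 > 0.25
  expect_false(identified_in_sample("T1", qual2, list(ctrl3), p))
})

test_that("the toy experiment yields exactly one consensus candidate, matching the brute-force oracle", {
  rt <- toy_tables()
  cs <- consensus_candidates(rt, "A")
  expect_equal(cs$candidates$accession, "TGT")
  expect_equal(cs$candidates$hit_count, 6L)
  expect_equal(cs$candidates$hit_pattern, "111111")
  expect_equal(cs$candidates$total_psm, 60L)
  expect_equal(oracle_candidates(rt, "A"), "TGT")

  # evaluated table records the non-members' hit counts
  evald <- cs$evaluated
  expect_equal(evald$hit_count[evald$accession == "BKG"], 0L)
  expect_equal(evald$hit_count[evald$accession == "LOWEV"], 0L)
  expect_equal(evald$hit_count[evald$accession == "TWORUN"], 2L)
  expect_equal(evald$hit_count[evald$accession == "NONSPEC"], 0L)

  # boundary: 4-of-6 is a member, 3-of-6 is not
  p3 <- filter_params(min_hits = 3)
  expect_true("TWORUN" %in% consensus_candidates(rt, "A", filter_params(min_hits = 2))$candidates$accession)
  expect_false("TWORUN" %in% consensus_candidates(rt, "A", p3)$candidates$accession)
})

test_that("audit table records every ratio and gate decision", {
  cs <- consensus_candidates(toy_tables(), "A", audit = TRUE)
  aud <- cs$audit
  # one row per (protein, qualifying slot, exclusion sample)
  expect_true(all(c("ratio", "evidence_pass", "excluded", "identified")
                  %in% names(aud)))
  bkg <- aud[aud$accession == "BKG" & aud$exclusion_sample == "R1_ctrl" &
               aud$qualifying_sample == "R1_probe", ]
  expect_equal(bkg$ratio, 0.5)
  expect_true(bkg$excluded)
  expect_false(any(aud$identified[aud$accession == "LOWEV"]))
  expect_false(any(aud$evidence_pass[aud$accession == "LOWEV"]))
})

test_that("configuration errors: no qualifying samples, or provably empty candidate sets", {
  rt <- toy_tables()
  expect_error(consensus_candidates(rt, "Z"), class = "competeMS_design_error")
  # 6 slots, min_hits 6: allowed (warns on the unexpected slot count)
  expect_warning(consensus_candidates(rt, "A", filter_params(min_hits = 6,
                   expected_qualifying_samples = 8)),
                 "qualifying slots")
  expect_error(suppressWarnings(consensus_candidates(
    rt, "A", filter_params(min_hits = 7, expected_qualifying_samples = 8))),
    class = "competeMS_config_error")
})

test_that("candidates are monotone in threshold, consensus depth and exclusion set", {
  for (seed in 1:25) {
    rt <- random_experiment(seed)
    strict <- consensus_candidates(rt, "A", filter_params(ratio_threshold = 0.1))
    loose <- consensus_candidates(rt, "A", filter_params(ratio_threshold = 0.5))
    expect_true(all(strict$candidates$accession %in% loose$candidates$accession))

    deep <- consensus_candidates(rt, "A", filter_params(min_hits = 5))
    shallow <- consensus_candidates(rt, "A", filter_params(min_hits = 3))
    expect_true(all(deep$candidates$accession %in% shallow$candidates$accession))

    # removing an exclusion sample can only grow the candidate set
    pruned <- rt
    pruned$tables <- rt$tables[setdiff(names(rt$tables),
                                       sprintf("R%d_comp", 1:3))]
    grown <- suppressWarnings(consensus_candidates(pruned, "A"))
    full <- consensus_candidates(rt, "A")
    expect_true(all(full$candidates$accession %in% grown$candidates$accession))
  }
})

test_that("identification decisions are invariant to scaling all PSM counts in a run", {
  for (seed in 1:10) {
    rt <- random_experiment(seed)
    scaled <- rt
    for (sid in names(scaled$tables)) {
      tab <- scaled$tables[[sid]]
      tab$psm_count <- tab$psm_count * 7L
      # keep count invariants intact under scaling
      scaled$tables[[sid]] <- tab
    }
    a <- consensus_candidates(rt, "A")$candidates$accession
    b <- consensus_candidates(scaled, "A")$candidates$accession
    expect_equal(b, a)
  }
})
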