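test_that("a canonical competition design round-trips through disk and validates", {
  design <- small_design()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design(design, path)
  back <- read_design(path)
  expect_s3_class(back, "sample_design")
  expect_equal(back$sample_id, design$sample_id)
  expect_equal(back$run_id, design$run_id)
  expect_equal(back$role, design$role)
})

test_that("design validation rejects malformed designs with informative errors", {
  base <- tibble::as_tibble(small_design(1))

  # empty design
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\trun_id\tprobe\trole", empty)
  expect_error(read_design(empty), class = "competeMS_design_error")

  # duplicate sample_id, named in the message
  dup <- dplyr::bind_rows(base, base[1, ])
  expect_error(sample_design(dup), "R1_probe",
               class = "competeMS_design_error")

  # two probe_only samples for the same (run, probe)
  extra <- base[1, ]; extra$sample_id <- "R1_probe2"
  expect_error(sample_design(dplyr::bind_rows(base, extra)),
               class = "competeMS_design_error")

  # unknown role vocabulary
  bad <- base; bad$role[3] <- "mock_control"
  expect_error(sample_design(bad), class = "competeMS_vocabulary_error")

  # probe-dependent role carrying NONE
  bad <- base; bad$probe[1] <- "NONE"
  expect_error(sample_design(bad), class = "competeMS_design_error")

  # probe_only run without any exclusion-side sample
  solo <- base[base$role %in% c("probe_only", "inactive_competition"), ]
  expect_error(sample_design(solo), class = "competeMS_design_error")
})

test_that("protein tables parse, and invariant-violating rows are rejected by file/line/field", {
  design <- small_design(1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tgene_symbol\tpsm_count\tn_peptides\tn_unique_peptides",
               "P12345\tSTING\t12\t5\t3"), path)
  rt <- read_run_tables(c(R1_probe = path), design)
  tab <- rt$tables$R1_probe
  expect_equal(tab$accession, "P12345")
  expect_equal(tab$psm_count, 12L)
  expect_equal(tab$n_peptides, 5L)
  expect_equal(tab$n_unique_peptides, 3L)

  # unique > peptides
  writeLines(c("accession\tgene_symbol\tpsm_count\tn_peptides\tn_unique_peptides",
               "P1\tX\t10\t3\t4"), path)
  err <- expect_error(read_run_tables(c(R1_probe = path), design),
                      class = "competeMS_evidence_error")
  expect_match(conditionMessage(err), "line 2")
  expect_match(conditionMessage(err), "n_unique_peptides")

  # negative count
  writeLines(c("accession\tgene_symbol\tpsm_count\tn_peptides\tn_unique_peptides",
               "P1\tX\t-2\t1\t1"), path)
  err <- expect_error(read_run_tables(c(R1_probe = path), design),
                      class = "competeMS_parse_error")
  expect_match(conditionMessage(err), "psm_count")

  # duplicate accession names accession and sample
  writeLines(c("accession\tgene_symbol\tpsm_count\tn_peptides\tn_unique_peptides",
               "P1\tX\t5\t2\t1", "P1\tX\t6\t2\t1"), path)
  err <- expect_error(read_run_tables(c(R1_probe = path), design),
                      class = "competeMS_evidence_error")
  expect_match(conditionMessage(err), "P1")
  expect_match(conditionMessage(err), "R1_probe")

  # zero-PSM rows violate absence-by-omission
  writeLines(c("accession\tgene_symbol\tpsm_count\tn_peptides\tn_unique_peptides",
               "P1\tX\t0\t0\t0"), path)
  expect_error(read_run_tables(c(R1_probe = path), design),
               class = "competeMS_evidence_error")

  # sample id not in the design
  writeLines(c("accession\tgene_symbol\tpsm_count\tn_peptides\tn_unique_peptides",
               "P1\tX\t5\t2\t1"), path)
  expect_error(read_run_tables(c(S_unknown = path), design),
               class = "competeMS_unknown_sample_error")
})

test_that("write/read round-trip preserves the evidence multiset", {
  rt <- random_experiment(seed = 7)
  dir <- withr::local_tempdir()
  paths <- write_run_tables(rt, dir)
  dpath <- file.path(dir, "design.tsv")
  write_design(rt$design, dpath)
  back <- read_run_tables(paths, read_design(dpath))
  expect_equal(names(back$tables), names(rt$tables))
  for (sid in names(rt$tables)) {
    a <- dplyr::arrange(rt$tables[[sid]], accession)
    b <- dplyr::arrange(back$tables[[sid]], accession)
    expect_equal(as.data.frame(b), as.data.frame(a))
  }
})

test_that("candidate output is deterministic, rank-ordered, and header-only when empty", {
  cs <- consensus_candidates(toy_tables(), "A")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cs, p1)
  write_candidates(cs, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  lines <- readLines(p1)
  expect_match(lines[1], "^accession\t")

  # empty candidate set
  empty <- cs
  empty$candidates <- cs$candidates[0, ]
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(empty, p3)
  expect_length(readLines(p3), 1)

  # accession-per-line export round-trip
  p4 <- withr::local_tempfile(fileext = ".txt")
  write_accessions(cs, p4)
  expect_equal(read_accessions(p4), sort(cs$candidates$accession))
})
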