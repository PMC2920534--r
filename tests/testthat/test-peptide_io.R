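test_that("read_panels groups, merges duplicates and keeps first-seen order", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tantibody_class\tsequence\tcopy_number",
               "A\tIgG\tTGVRGQRISQ\t9",
               "A\tIgG\tQNPGETSKMN\t6",
               "A\tIgG\tKYRWYK\t3"), tsv)
  pan <- read_panels(tsv)
  expect_equal(nrow(pan), 3)
  expect_equal(unique(pan$panel_id), "A/IgG")
  expect_equal(sum(pan$copy_number), 18)
  expect_equal(pan$sequence, c("TGVRGQRISQ", "QNPGETSKMN", "KYRWYK"))

  writeLines(c("patient_id\tantibody_class\tsequence\tcopy_number",
               "A\tIgG\tKYRWYK\t2",
               "A\tIgG\tAEPPFEF\t1",
               "A\tIgG\tKYRWYK\t1"), tsv)
  pan <- read_panels(tsv)
  expect_equal(nrow(pan), 2)
  expect_equal(pan$copy_number[pan$sequence == "KYRWYK"], 3)
  expect_equal(pan$sequence[1], "KYRWYK")  # order of first occurrence
})

test_that("read_panels rejects illegal characters and malformed rows with line numbers", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tantibody_class\tsequence\tcopy_number",
               "A\tIgG\tKYRWYK\t1",
               "A\tIgG\tKYRW1K\t1"), tsv)
  expect_error(read_panels(tsv), "Illegal character '1'.*line 3",
               class = "mimoscan_parse_error")
  writeLines(c("patient_id\tantibody_class\tsequence\tcopy_number",
               "A\tIgG\tKYRBYK\t1"), tsv)
  expect_error(read_panels(tsv), "'B'", class = "mimoscan_parse_error")
  writeLines(c("patient_id\tantibody_class\tsequence\tcopy_number",
               "A\tIgG\tKYRWYK\t0"), tsv)
  expect_error(read_panels(tsv), "copy_number.*line 2")
  writeLines(c("patient_id\tantibody_class\tsequence",
               "A\t\tKYRWYK"), tsv)
  expect_error(read_panels(tsv), "line 2")
  # copy_number column optional, defaults to 1
  writeLines(c("patient_id\tantibody_class\tsequence",
               "A\tIgG\tKYRWYK"), tsv)
  expect_equal(read_panels(tsv)$copy_number, 1L)
})

test_that("panel round trip through TSV and FASTA preserves values exactly", {
  pan <- table1_panels()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_panels(pan, tsv)
  back <- read_panels(tsv)
  expect_equal(back$sequence, pan$sequence)
  expect_equal(back$copy_number, pan$copy_number)
  expect_equal(back$panel_id, pan$panel_id)

  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A|IgG|9", "TGVRGQRISQ", ">A|IgG|6", "QNPGETSKMN",
               ">A|IgM|2", "aeppfef"), fa)
  pf <- read_panels(fa)
  expect_equal(pf$sequence, c("TGVRGQRISQ", "QNPGETSKMN", "AEPPFEF"))
  expect_equal(pf$copy_number, c(9L, 6L, 2L))
  expect_equal(pf$panel_id, c("A/IgG", "A/IgG", "A/IgM"))
})

test_that("shipped reference fixture equals the in-code constructor", {
  path <- system.file("extdata", "table1_panels.tsv", package = "mimoscan")
  expect_true(file.exists(path))
  shipped <- read_panels(path)
  built <- table1_panels()
  expect_equal(shipped$sequence, built$sequence)
  expect_equal(shipped$copy_number, built$copy_number)
  expect_equal(shipped$panel_id, built$panel_id)
})

test_that("read_proteome folds case, computes lengths and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 test protein", "mktay"), fa)
  pr <- read_proteome(fa)
  expect_equal(pr$sequence, "MKTAY")
  expect_equal(pr$length_aa, 5L)
  expect_equal(pr$protein_id, "P1")
  expect_equal(pr$description, "test protein")

  writeLines(c(">P1 a", "MKTAY", ">P1 b", "MKTAY"), fa)
  expect_error(read_proteome(fa), "Duplicate protein id.*P1")
  writeLines(character(0), fa)
  expect_error(read_proteome(fa), "empty")
  # order preserved
  writeLines(c(">Z1", "MKTAY", ">A1", "WWWWW"), fa)
  expect_equal(read_proteome(fa)$protein_id, c("Z1", "A1"))
})

test_that("external match tables map outfmt-6 columns and validate coordinates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pep1\tP1\t100\t0\t0\t0\t1\t4\t10\t13\t1e-1\t20", tsv)
  m <- read_external_matches(tsv)
  expect_equal(m$peptide_id, "pep1")
  expect_equal(m$protein_id, "P1")
  expect_equal(m$align_start, 10L)
  expect_equal(m$align_end, 13L)

  writeLines("pep1\tP1\t100\t0\t0\t0\t1\t4\t13\t10\t1e-1\t20", tsv)
  expect_error(read_external_matches(tsv), "row 1")
  file.create(tsv2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_external_matches(tsv2)), 0)
})

test_that("hit tables written in the outfmt-6 dialect re-import losslessly", {
  prot <- make_proteome("MTDAAPWSKVTQ", "P1")
  pan <- make_panel(c("VPWSKPW", "TDAAPWSKVT"), patient_id = "D")
  hits <- search_panels(pan, prot, match_params(min_exact_window = 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, path)
  back <- external_to_hits(read_external_matches(path), pan, prot)
  expect_equal(back$panel_id, hits$panel_id)
  expect_equal(back$sequence, hits$sequence)
  expect_equal(back$p_start, hits$p_start)
  expect_equal(back$p_end, hits$p_end)
  expect_equal(back$matched_substring, hits$matched_substring)
})

test_that("candidate reports round-trip and are byte-identical across re-writes", {
  res <- tibble::tibble(
    panel_id = c("A/IgG", "A/IgG"), protein_id = c("P2", "P1"),
    length_aa = c(403L, 14507L), n = c(3L, 3L), k = c(2L, 1L),
    k_eff = c(2L, 1L), shared_motif = c(NA_character_, NA),
    p_binomial = c(1.938436e-4, 0.7603), p_fisher = c(1.242236e-3, 0.21),
    other_matches = c(0L, 3L), other_total = c(67L, 67L),
    q_value = c(3.2e-5, NA), flags = c("", "LENGTH_SUSPECT"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, tsv)
  back <- read_report(tsv)
  expect_equal(back$p_binomial, signif(res$p_binomial, 6))
  expect_equal(back$flags, c("", "LENGTH_SUSPECT"))
  expect_equal(back$protein_id, res$protein_id)
  # JSON sibling is the exact mirror
  backj <- read_report(sub("\\.tsv$", ".json", tsv))
  expect_identical(backj$p_binomial, res$p_binomial)
  # byte-identical on re-run, order stable under ties
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, tsv2)
  expect_identical(readLines(tsv), readLines(tsv2))
  # empty report: header only
  write_report(res[0, ], tsv)
  expect_equal(length(readLines(tsv)), 1)
  expect_equal(nrow(read_report(tsv)), 0)
})

test_that("report floats use 6 significant digits, scientific below 1e-4", {
  expect_equal(mimoscan:::format_report_num(c(0.00806, 1.938436e-4)),
               c("0.00806", "0.000193844"))
  expect_equal(mimoscan:::format_report_num(3.25e-5), "3.25000e-05")
  expect_equal(mimoscan:::format_report_num(c(1, 0, NA)), c("1", "0", "NA"))
})
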