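audit_residues <- tibble::tibble(
  entity = c("1", "1", "2"),
  resno = c(213L, 120L, 44L),
  resid = c("ARG", "HIS", "ASP"))

test_that("NMR-STAR and TSV fixtures parse to identical tables", {
  spec <- fixture_spec("assignments", seed = 5)
  f_star <- tempfile(fileext = ".str")
  f_tsv <- tempfile(fileext = ".tsv")
  writeLines(make_assignment_fixture(spec, audit_residues,
                                     format = "nmrstar"), f_star)
  writeLines(make_assignment_fixture(spec, audit_residues,
                                     format = "tsv"), f_tsv)
  a <- read_assignments(f_star)
  b <- read_assignments(f_tsv)
  expect_identical(tibble::as_tibble(a)[c("entity", "resno", "resid", "atom")],
                   tibble::as_tibble(b)[c("entity", "resno", "resid", "atom")])
  expect_s3_class(a, "assignment_table")
  expect_gt(nrow(a), 0L)
})

test_that("an empty or loop-free STAR file is a format error", {
  f <- tempfile(fileext = ".str")
  writeLines(c("data_x", "save_y", "save_"), f)
  expect_error(read_assignments(f, format = "nmrstar"), "loop")
  writeLines(c("data_x", "loop_", "   _Atom_chem_shift.Seq_ID",
               "   _Atom_chem_shift.Comp_ID", "   _Atom_chem_shift.Atom_ID",
               "   _Atom_chem_shift.Val", "stop_"), f)
  expect_error(read_assignments(f, format = "nmrstar"), "empty")
})

test_that("small TSV fixtures load row-for-row", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("entity\tresidue\tres_type\tatom\tshift",
               paste("1", 44:48, "ASP", "CG", "41.2", sep = "\t")), f)
  tab <- read_assignments(f)
  expect_identical(nrow(tab), 5L)
})

test_that("duplicate assignment keys are dropped with a warning", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("entity\tresidue\tres_type\tatom\tshift",
               "1\t44\tASP\tCG\t41.2",
               "1\t44\tASP\tCG\t41.3"), f)
  expect_warning(tab <- read_assignments(f), "duplicate")
  expect_identical(nrow(tab), 1L)
})

test_that("a known dropped-nucleus set is recovered exactly", {
  drop <- tibble::tibble(entity = c("2", "1", "1", "1"),
                         resno = c(44L, 213L, 213L, 213L),
                         atom = c("CG", "CZ", "NH1", "HH11"))
  f <- tempfile(fileext = ".str")
  writeLines(make_assignment_fixture(fixture_spec("assignments", seed = 1),
                                     audit_residues, drop,
                                     format = "nmrstar"), f)
  miss <- find_missing_assignments(read_assignments(f),
                                   c("2:44:ASP", "1:213:ARG", "1:120:HIS"))
  got <- paste(miss$entity, miss$resno, miss$nucleus)
  want <- paste(drop$entity, drop$resno, drop$atom)
  expect_setequal(got, want)
})

test_that("fully assigned residues yield an empty report", {
  f <- tempfile(fileext = ".tsv")
  writeLines(make_assignment_fixture(fixture_spec("assignments", seed = 2),
                                     audit_residues, format = "tsv"), f)
  miss <- find_missing_assignments(read_assignments(f),
                                   c("2:44:ASP", "1:213:ARG"))
  expect_identical(nrow(miss), 0L)
})

test_that("a random dropped subset equals the generator's drop log", {
  full <- dplyr::inner_join(audit_residues, expected_sidechain_nuclei(),
                            by = "resid", relationship = "many-to-many")
  drop <- withr::with_seed(3, dplyr::slice_sample(full, prop = 0.2))
  f <- tempfile(fileext = ".tsv")
  writeLines(make_assignment_fixture(fixture_spec("assignments", seed = 3),
                                     audit_residues,
                                     drop[c("entity", "resno", "atom")],
                                     format = "tsv"), f)
  miss <- find_missing_assignments(
    read_assignments(f), audit_residues)
  expect_setequal(paste(miss$entity, miss$resno, miss$nucleus),
                  paste(drop$entity, drop$resno, drop$atom))
})

test_that("adding an assignment never grows the missing list", {
  drop <- tibble::tibble(entity = "2", resno = 44L, atom = c("CG", "OD1"))
  spec <- fixture_spec("assignments", seed = 4)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(make_assignment_fixture(spec, audit_residues, drop,
                                     format = "tsv"), f1)
  writeLines(make_assignment_fixture(spec, audit_residues, drop[1, ],
                                     format = "tsv"), f2)
  m1 <- find_missing_assignments(read_assignments(f1), "2:44:ASP")
  m2 <- find_missing_assignments(read_assignments(f2), "2:44:ASP")
  expect_true(all(paste(m2$entity, m2$resno, m2$nucleus) %in%
                    paste(m1$entity, m1$resno, m1$nucleus)))
  expect_lt(nrow(m2), nrow(m1))
})

test_that("residue-type mismatches between selector and table warn", {
  f <- tempfile(fileext = ".tsv")
  writeLines(make_assignment_fixture(fixture_spec("assignments", seed = 6),
                                     audit_residues, format = "tsv"), f)
  tab <- read_assignments(f)
  expect_warning(find_missing_assignments(tab, "2:44:GLU"), "match")
})

test_that("numbering offsets reconcile selector and deposition numbering", {
  drop <- tibble::tibble(entity = "2", resno = 44L, atom = "CG")
  f <- tempfile(fileext = ".tsv")
  writeLines(make_assignment_fixture(fixture_spec("assignments", seed = 7),
                                     audit_residues, drop,
                                     format = "tsv"), f)
  tab <- read_assignments(f)
  miss <- find_missing_assignments(tab, "2:34:ASP", offset = 10L)
  expect_identical(miss$nucleus, "CG")
  expect_identical(miss$resno, 34L)
})
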