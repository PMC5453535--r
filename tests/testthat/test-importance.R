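test_that("importance equals the disjunction of its three flags", {
  ens <- straddle <- read_fixture(make_ensemble_fixture(
    fixture_spec("ensemble", distance = 3.6, n_models = 4L, jitter_sd = 0.2,
                 seed = 8)))
  cfg <- detection_config(sb_mode = "group_center")
  prof <- residue_sasa_profile(ens)
  sb <- summarize_interactions(ens, cfg, "salt_bridge")
  # the fixture has no explicit hydrogens: donors are skipped with warnings
  hb <- suppressWarnings(summarize_interactions(ens, cfg, "hydrogen_bond"))
  rec <- classify_important_residues(prof, list(sb, hb))
  expect_identical(rec$important,
                   rec$in_salt_bridge | rec$in_hydrogen_bond | rec$buried)
  # both bridge partners are flagged through the salt-bridge route
  expect_true(all(rec$in_salt_bridge))
})

test_that("an exposed contact-free residue is not important", {
  model <- dplyr::bind_rows(
    fixture_atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
    fixture_atom_row("A", 1, "ALA", "CB", "C", 1.5, 0, 0))
  prof <- residue_sasa_profile(model)
  rec <- classify_important_residues(
    prof, tibble::tibble(kind = character()))
  expect_false(rec$important)
})

test_that("a single hydrogen bond suffices via the rule's disjunction", {
  ens <- read_fixture(make_hbond_fixture(
    fixture_spec("hbond", distance = 2.7, angle = 10)))
  prof <- residue_sasa_profile(ens)
  hb <- summarize_interactions(ens, detection_config(), "hydrogen_bond")
  rec <- classify_important_residues(prof, hb)
  lys <- rec[rec$resid == "LYS", ]
  expect_true(lys$in_hydrogen_bond)
  expect_false(lys$in_salt_bridge)
  expect_true(lys$important)
})

test_that("backbone-O acceptors do not flag the acceptor's side chain", {
  summ <- tibble::tibble(
    kind = "hydrogen_bond",
    chain_d = "A", resno_d = 1L, icode_d = "", resid_d = "LYS",
    donor_atom = "NZ", hydrogen_atom = "HZ1",
    chain_a = "B", resno_a = 5L, icode_a = "", resid_a = "GLN",
    acceptor_atom = "O")
  prof <- tibble::tibble(
    chain = c("A", "B"), resno = c(1L, 5L), icode = "",
    resid = c("LYS", "GLN"), sasa_ratio = c(0.9, 0.9))
  rec <- classify_important_residues(prof, summ)
  expect_true(rec$in_hydrogen_bond[rec$chain == "A"])
  expect_false(rec$in_hydrogen_bond[rec$chain == "B"])
})

test_that("mutation cross-referencing matches positions on the SMN chain only", {
  rec <- tibble::tibble(
    chain = c("B", "A"), resno = c(44L, 44L), icode = "",
    resid = c("ASP", "ARG"), sasa_ratio = c(0.2, 0.9),
    in_salt_bridge = TRUE, in_hydrogen_bond = FALSE,
    buried = c(TRUE, FALSE), important = TRUE)
  matched <- cross_reference_mutations(rec, sma_mutations(), chains = "B") |>
    suppressWarnings()
  expect_identical(unique(matched$chain), "B")
  expect_identical(matched$label, "D44V")

  expect_identical(
    nrow(suppressWarnings(
      cross_reference_mutations(rec, sma_mutations()[0, ]))), 0L)
  expect_warning(
    cross_reference_mutations(
      rec, tibble::tibble(position = 999L, wt = "G", mut = "R",
                          label = "G999R", source = "user")),
    "999")
})

test_that("the packaged catalogue covers the expected positions and parses", {
  cat_tbl <- sma_mutations()
  expect_true(all(c(44L, 92L, 102L, 111L, 116L, 134L, 136L) %in%
                    cat_tbl$position))
  expect_true(all(cat_tbl$wt != cat_tbl$mut))
  # labels round-trip through the parser
  for (i in seq_len(nrow(cat_tbl))) {
    if (cat_tbl$mut[i] == "X") next
    ann <- annotate_mutation_impact(cat_tbl$label[i])
    expect_identical(ann$position, cat_tbl$position[i])
    expect_identical(ann$wt, cat_tbl$wt[i])
    expect_identical(ann$mut, cat_tbl$mut[i])
  }
})

test_that("impact typology follows the residue-chemistry table", {
  bridge <- tibble::tibble(kind = "salt_bridge", chain_a = "A",
                           resno_a = 213L, chain_b = "B", resno_b = 44L)
  d44v <- annotate_mutation_impact("D44V", bridge)
  expect_identical(d44v$category, "charge_removal")
  expect_identical(d44v$predicted_sign_change, "attraction_lost")

  hb <- tibble::tibble(kind = "hydrogen_bond", chain_d = "B",
                       resno_d = 127L, chain_a = "B", resno_a = 134L)
  e134k <- annotate_mutation_impact("E134K", hb)
  expect_identical(e134k$category, "charge_reversal_neg_to_pos")
  expect_identical(e134k$predicted_sign_change, "attraction_to_repulsion")

  q136e <- annotate_mutation_impact("Q136E", hb)
  expect_identical(q136e$category, "charge_reversal_donor_to_neg")
  expect_identical(q136e$predicted_sign_change, "attraction_to_repulsion")

  a111g <- annotate_mutation_impact("A111G")
  expect_identical(a111g$category, "hydrophobic_removal")
  expect_identical(a111g$predicted_sign_change, "none")

  w102x <- annotate_mutation_impact(
    tibble::tibble(position = 102L, wt = "W", mut = "X", label = "W102X"))
  expect_identical(w102x$category, "truncation")

  i116f <- annotate_mutation_impact("I116F")
  expect_identical(i116f$category, "other")

  expect_error(annotate_mutation_impact("D44Z"), "unknown")
})

test_that("impact annotation is a pure, stable function of its inputs", {
  bridge <- tibble::tibble(kind = "salt_bridge", chain_a = "A",
                           resno_a = 213L, chain_b = "B", resno_b = 44L)
  a1 <- annotate_mutation_impact("D44V", bridge)
  a2 <- annotate_mutation_impact("D44V", bridge)
  expect_identical(a1, a2)
  # without interactions the same substitution predicts no sign change
  expect_identical(annotate_mutation_impact("D44V")$predicted_sign_change,
                   "none")
})
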