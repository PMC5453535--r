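test_that("charged groups carry the field-standard atoms and polarities", {
  ens <- read_fixture(make_salt_bridge_fixture(fixture_spec("salt_bridge")))
  g <- charged_groups(get_model(ens, 1))
  expect_identical(nrow(g), 2L)
  expect_setequal(g$polarity, c("negative", "positive"))
  asp <- g[g$resid == "ASP", ]
  expect_setequal(asp$atoms[[1]]$atom, c("OD1", "OD2"))
  # degenerate mean: a lone OD1 becomes the center
  m <- get_model(ens, 1)
  m2 <- dplyr::filter(m, .data$atom != "OD2")
  g2 <- charged_groups(m2)
  asp2 <- g2[g2$resid == "ASP", ]
  od1 <- dplyr::filter(m2, .data$atom == "OD1")
  expect_equal(c(asp2$cx, asp2$cy, asp2$cz), c(od1$x, od1$y, od1$z))
})

test_that("a residue with every group atom missing is skipped with warning", {
  ens <- read_fixture(make_salt_bridge_fixture(fixture_spec("salt_bridge")))
  m <- dplyr::filter(get_model(ens, 1), !.data$atom %in% c("OD1", "OD2"))
  expect_warning(g <- charged_groups(m), "missing")
  expect_identical(g$resid, "LYS")
})

test_that("group-center bridges respect the inclusive 4.0 A cutoff", {
  cfg <- detection_config(sb_mode = "group_center")
  for (case in list(c(3.8, 1), c(4.0, 1), c(4.2, 0))) {
    ens <- read_fixture(make_salt_bridge_fixture(
      fixture_spec("salt_bridge", distance = case[1])))
    sb <- detect_salt_bridges(get_model(ens, 1), cfg)
    expect_identical(nrow(sb), as.integer(case[2]))
    if (nrow(sb) == 1L) {
      expect_equal(sb$distance, case[1], tolerance = 2e-3)
      expect_identical(sb$scope, "intramolecular")
    }
  }
})

test_that("both detectors agree with brute-force oracles on random fixtures", {
  for (seed in c(3, 17, 42)) {
    model <- random_charged_model(30, seed = seed)
    got_ap <- detect_salt_bridges(model, detection_config()) |>
      dplyr::arrange(.data$resno_a, .data$resno_b, .data$atom_a,
                     .data$atom_b)
    exp_ap <- oracle_salt_bridges_atom_pair(model)
    expect_identical(nrow(got_ap), nrow(exp_ap))
    expect_identical(got_ap$resno_a, exp_ap$resno_a)
    expect_identical(got_ap$atom_a, exp_ap$atom_a)
    expect_identical(got_ap$atom_b, exp_ap$atom_b)
    expect_equal(got_ap$distance, exp_ap$distance, tolerance = 1e-12)

    got_gc <- detect_salt_bridges(
      model, detection_config(sb_mode = "group_center")) |>
      dplyr::arrange(.data$resno_a, .data$resno_b)
    exp_gc <- oracle_salt_bridges_group_center(model)
    expect_identical(got_gc$resno_a, exp_gc$resno_a)
    expect_equal(got_gc$distance, exp_gc$distance, tolerance = 1e-12)

    hmodel <- random_hbond_model(24, seed = seed)
    got_hb <- detect_hydrogen_bonds(hmodel, detection_config()) |>
      dplyr::arrange(.data$resno_d, .data$resno_a, .data$hydrogen_atom,
                     .data$acceptor_atom)
    exp_hb <- oracle_hbonds(hmodel)
    expect_identical(nrow(got_hb), nrow(exp_hb))
    expect_equal(got_hb$d_da, exp_hb$d_da, tolerance = 1e-12)
    expect_equal(got_hb$angle_adh, exp_hb$angle, tolerance = 1e-9)
  }
})

test_that("detections grow monotonically with every cutoff", {
  model <- random_charged_model(25, seed = 9)
  counts <- purrr::map_int(c(2, 3, 4, 5, 7), function(cut) {
    nrow(detect_salt_bridges(model, detection_config(sb_cutoff = cut)))
  })
  expect_true(all(diff(counts) >= 0))

  hmodel <- random_hbond_model(24, seed = 9)
  for (da in c(2.5, 3.0, 3.5)) {
    n_prev <- -1L
    for (ang in c(15, 30, 60)) {
      n <- nrow(detect_hydrogen_bonds(
        hmodel, detection_config(hb_da_cutoff = da,
                                 hb_angle_cutoff = ang)))
      expect_gte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("no detected interaction pairs a residue with itself", {
  model <- random_charged_model(30, seed = 21)
  sb <- detect_salt_bridges(model, detection_config(sb_cutoff = 12))
  expect_true(all(sb$chain_a != sb$chain_b | sb$resno_a != sb$resno_b))
  hmodel <- random_hbond_model(24, seed = 21)
  hb <- detect_hydrogen_bonds(
    hmodel, detection_config(hb_da_cutoff = 8, hb_angle_cutoff = 90))
  expect_true(all(hb$chain_d != hb$chain_a | hb$resno_d != hb$resno_a))
})

test_that("hydrogen-bond criteria are inclusive at both boundaries", {
  for (case in list(list(c(2.63, 18.83), 1), list(c(3.0, 30), 1),
                    list(c(2.9, 35), 0), list(c(3.2, 10), 0),
                    list(c(2.5, 45), 0))) {
    ens <- read_fixture(make_hbond_fixture(
      fixture_spec("hbond", distance = case[[1]][1], angle = case[[1]][2])))
    hb <- detect_hydrogen_bonds(get_model(ens, 1))
    expect_identical(nrow(hb), as.integer(case[[2]]))
  }
})

test_that("detected geometry matches the engineered values to 2 decimals", {
  ens <- read_fixture(make_hbond_fixture(
    fixture_spec("hbond", distance = 2.63, angle = 18.83)))
  hb <- detect_hydrogen_bonds(get_model(ens, 1))
  expect_equal(hb$d_da, 2.63, tolerance = 0.005)
  expect_equal(hb$angle_adh, 18.83, tolerance = 0.05)
  expect_identical(hb$scope, "intermolecular")
  expect_identical(hb$donor_atom, "NZ")
  expect_identical(hb$acceptor_atom, "OE1")
})

test_that("a hydrogen-free model yields no donors and a warning", {
  ens <- read_fixture(make_salt_bridge_fixture(fixture_spec("salt_bridge")))
  m <- get_model(ens, 1)
  expect_warning(inv <- donor_acceptor_inventory(m), "no bound hydrogen")
  expect_identical(nrow(inv$donors), 0L)
})

test_that("acceptor scope switch removes backbone carbonyl acceptors", {
  hmodel <- random_hbond_model(24, seed = 2)
  inv_bb <- donor_acceptor_inventory(hmodel, detection_config())
  inv_sc <- donor_acceptor_inventory(
    hmodel, detection_config(hb_acceptor_scope = "sidechain_only"))
  expect_true(any(inv_bb$acceptors$is_backbone))
  expect_false(any(inv_sc$acceptors$is_backbone))
})

test_that("a lysine ammonium contributes three donor pairs on NZ", {
  hmodel <- random_hbond_model(2, seed = 1)
  inv <- donor_acceptor_inventory(hmodel, detection_config())
  nz <- dplyr::filter(inv$donors, .data$donor_atom == "NZ")
  expect_identical(nrow(nz), 3L)
  expect_setequal(nz$hydrogen_atom, c("HZ1", "HZ2", "HZ3"))
})

test_that("distance series statistics follow the closed form", {
  base <- dplyr::bind_rows(
    fixture_atom_row("A", 1, "ASP", "OD1", "O", 0, 0, 0),
    fixture_atom_row("A", 2, "LYS", "NZ", "N", 2, 0, 0))
  two <- dplyr::bind_rows(base,
                          dplyr::mutate(base, model = 2L,
                                        x = .data$x * 2))
  ds <- atom_pair_distance_series(two, "A:1:OD1", "A:2:NZ")
  g <- glance(ds)
  expect_equal(g$distance_mean, 3)
  expect_equal(g$distance_std, 1)  # population convention
  g2 <- glance(atom_pair_distance_series(
    two, "A:1:OD1", "A:2:NZ", config = detection_config(sd = "sample")))
  expect_equal(g2$distance_std, sqrt(2))

  identical_models <- dplyr::bind_rows(base, dplyr::mutate(base, model = 2L))
  expect_equal(
    glance(atom_pair_distance_series(identical_models,
                                     "A:1:OD1", "A:2:NZ"))$distance_std, 0)
})

test_that("ambiguous selectors error and scope classification is by chain", {
  base <- dplyr::bind_rows(
    fixture_atom_row("A", 1, "ASP", "OD1", "O", 0, 0, 0),
    fixture_atom_row("A", 1, "ASP", "OD1", "O", 1, 0, 0),
    fixture_atom_row("B", 2, "LYS", "NZ", "N", 2, 0, 0))
  expect_error(atom_pair_distance_series(base, "A:1:OD1", "B:2:NZ"),
               "matches")

  sb <- tibble::tibble(chain_a = c("A", "B"), chain_b = c("A", "A"),
                       scope = NA_character_)
  out <- classify_contact_scope(sb)
  expect_identical(out$scope, c("intramolecular", "intermolecular"))
})
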