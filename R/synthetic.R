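# Deterministic synthetic fixtures: PDB text with engineered salt-bridge /
# hydrogen-bond geometry, occluded residues for burial tests, jittered
# multi-model ensembles, and assignment tables with controlled missingness.
# All randomness is seeded through the fixture spec; identical specs yield
# byte-identical text.

#' Specification of a synthetic fixture
#'
#' @param kind One of `"salt_bridge"`, `"hbond"`, `"burial"`, `"ensemble"`,
#'   `"assignments"`.
#' @param distance Target distance in Angstroms (group-center distance for
#'   salt bridges, donor-acceptor distance for hydrogen bonds).
#' @param angle Target ADH angle in degrees (hydrogen-bond fixtures).
#' @param shell_radius,shell_count Radius (Angstroms) and atom count of the
#'   occluding carbon shell (burial fixtures).
#' @param n_models Number of models (ensemble fixtures).
#' @param jitter_sd Isotropic per-atom Gaussian coordinate jitter, in
#'   Angstroms (ensemble fixtures).
#' @param seed Integer seed; fixes all randomness.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("salt_bridge", "hbond", "burial",
                                  "ensemble", "assignments"),
                         distance = 3.8, angle = 20,
                         shell_radius = 6, shell_count = 150,
                         n_models = 1L, jitter_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(distance > 0, jitter_sd >= 0, n_models >= 1L)
  structure(list(kind = kind, distance = distance, angle = angle,
                 shell_radius = shell_radius, shell_count = shell_count,
                 n_models = as.integer(n_models), jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, element = "") {
  name_field <- if (nchar(name) >= 4L) {
    sprintf("%-4s", substr(name, 1L, 4L))
  } else {
    sprintf(" %-3s", name)
  }
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_field, resid, chain, resno, x, y, z, occ, b, element)
}

atoms_to_pdb_lines <- function(atoms) {
  purrr::map_chr(seq_len(nrow(atoms)), function(i) {
    pdb_atom_line(i, atoms$atom[i], atoms$resid[i], atoms$chain[i],
                  atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i],
                  element = atoms$element[i])
  })
}

single_model_pdb_text <- function(atoms) {
  paste(c(atoms_to_pdb_lines(atoms), "END"), collapse = "\n")
}

fixture_atom <- function(chain, resno, resid, atom, element, x, y, z) {
  tibble::tibble(chain = chain, resno = as.integer(resno), resid = resid,
                 atom = atom, element = element, x = x, y = y, z = z)
}

# Minimal Asp-like residue whose carboxylate center sits at `center`.
asp_residue <- function(chain, resno, center = c(0, 0, 0)) {
  dplyr::bind_rows(
    fixture_atom(chain, resno, "ASP", "N", "N",
                 center[1] - 3.2, center[2], center[3] - 1.2),
    fixture_atom(chain, resno, "ASP", "CA", "C",
                 center[1] - 2.4, center[2], center[3] - 0.6),
    fixture_atom(chain, resno, "ASP", "C", "C",
                 center[1] - 3.0, center[2] + 1.0, center[3] + 0.2),
    fixture_atom(chain, resno, "ASP", "O", "O",
                 center[1] - 4.2, center[2] + 1.1, center[3] + 0.2),
    fixture_atom(chain, resno, "ASP", "CB", "C",
                 center[1] - 1.6, center[2], center[3]),
    fixture_atom(chain, resno, "ASP", "CG", "C",
                 center[1] - 0.8, center[2], center[3]),
    fixture_atom(chain, resno, "ASP", "OD1", "O",
                 center[1], center[2] + 1.0, center[3]),
    fixture_atom(chain, resno, "ASP", "OD2", "O",
                 center[1], center[2] - 1.0, center[3]))
}

# Minimal Lys-like residue whose NZ sits at `nz`.
lys_residue <- function(chain, resno, nz = c(4, 0, 0), with_h = FALSE) {
  out <- dplyr::bind_rows(
    fixture_atom(chain, resno, "LYS", "N", "N",
                 nz[1] + 3.2, nz[2], nz[3] - 1.2),
    fixture_atom(chain, resno, "LYS", "CA", "C",
                 nz[1] + 2.4, nz[2], nz[3] - 0.6),
    fixture_atom(chain, resno, "LYS", "C", "C",
                 nz[1] + 3.0, nz[2] + 1.0, nz[3] + 0.2),
    fixture_atom(chain, resno, "LYS", "O", "O",
                 nz[1] + 4.2, nz[2] + 1.1, nz[3] + 0.2),
    fixture_atom(chain, resno, "LYS", "CE", "C",
                 nz[1] + 1.4, nz[2], nz[3]),
    fixture_atom(chain, resno, "LYS", "NZ", "N", nz[1], nz[2], nz[3]))
  if (with_h) {
    out <- dplyr::bind_rows(
      out,
      fixture_atom(chain, resno, "LYS", "HZ1", "H",
                   nz[1] - 1.0, nz[2], nz[3]),
      fixture_atom(chain, resno, "LYS", "HZ2", "H",
                   nz[1] + 0.35, nz[2] + 0.95, nz[3]),
      fixture_atom(chain, resno, "LYS", "HZ3", "H",
                   nz[1] + 0.35, nz[2] - 0.95, nz[3]))
  }
  out
}

#' Salt-bridge fixture: an Asp/Lys pair at a controlled group distance
#'
#' Builds a two-residue single-model PDB whose Asp carboxylate center and
#' Lys NZ are exactly `spec$distance` apart (to numerical precision), on
#' one chain.
#'
#' @param spec A [fixture_spec()] with `kind = "salt_bridge"`.
#' @return PDB text (single string).
#' @export
make_salt_bridge_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$kind == "salt_bridge")
  atoms <- dplyr::bind_rows(
    asp_residue("A", 1L, center = c(0, 0, 0)),
    lys_residue("A", 2L, nz = c(spec$distance, 0, 0)))
  single_model_pdb_text(atoms)
}

#' Hydrogen-bond fixture: a donor/hydrogen/acceptor triple at controlled
#' geometry
#'
#' Builds a Lys donor (NZ with one HZ1 at 1.0 Angstrom) on chain A and a
#' Gln acceptor (OE1) on chain B such that the donor-acceptor distance and
#' the ADH angle at the donor equal the spec values.
#'
#' @param spec A [fixture_spec()] with `kind = "hbond"`; `distance` is
#'   d(D,A), `angle` the ADH angle in degrees (must be below 90).
#' @return PDB text (single string).
#' @export
make_hbond_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$kind == "hbond")
  if (spec$angle >= 90) {
    stop("ADH angles of 90 degrees or more are not constructible with a ",
         "1.0 Angstrom D-H bond pointing at the acceptor side")
  }
  d <- c(0, 0, 0)
  # PDB text carries three decimals; rounding can push the realized
  # distance/angle a hair past the request, which matters at an inclusive
  # cutoff boundary. Shrink the construction values until the geometry
  # recomputed from rounded coordinates is at or below the request.
  d_use <- spec$distance
  theta_use <- spec$angle
  for (iter in 1:50) {
    h <- round(c(1, 0, 0), 3)
    a <- round(c(d_use * cos(theta_use * pi / 180),
                 d_use * sin(theta_use * pi / 180), 0), 3)
    geom <- hbond_geometry(d, h, a)
    ok_d <- geom$d_da <= spec$distance
    ok_ang <- geom$angle_adh <= spec$angle
    if (ok_d && ok_ang) break
    if (!ok_d) d_use <- d_use - (geom$d_da - spec$distance + 1e-4)
    if (!ok_ang) {
      theta_use <- theta_use - (geom$angle_adh - spec$angle + 1e-3)
    }
  }

  donor <- dplyr::bind_rows(
    lys_residue("A", 1L, nz = d),
    fixture_atom("A", 1L, "LYS", "HZ1", "H", h[1], h[2], h[3]))
  # drop the backbone O of the donor far away so only the engineered
  # geometry is in range; shift whole backbone to z = -6
  donor <- dplyr::mutate(
    donor, z = ifelse(.data$atom %in% c("N", "CA", "C", "O"),
                      .data$z - 6, .data$z))
  acceptor <- dplyr::bind_rows(
    fixture_atom("B", 1L, "GLN", "N", "N", a[1] + 3.0, a[2], a[3] - 7.0),
    fixture_atom("B", 1L, "GLN", "CA", "C", a[1] + 2.6, a[2], a[3] - 6.4),
    fixture_atom("B", 1L, "GLN", "C", "C", a[1] + 3.4, a[2] + 1.0,
                 a[3] - 6.2),
    fixture_atom("B", 1L, "GLN", "O", "O", a[1] + 4.6, a[2] + 1.0,
                 a[3] - 6.2),
    fixture_atom("B", 1L, "GLN", "CD", "C", a[1] + 1.3, a[2], a[3]),
    fixture_atom("B", 1L, "GLN", "OE1", "O", a[1], a[2], a[3]))
  single_model_pdb_text(dplyr::bind_rows(donor, acceptor))
}

#' Burial fixture: a residue inside (or outside) an occluding carbon shell
#'
#' A central alanine surrounded by `spec$shell_count` carbon atoms on a
#' sphere of radius `spec$shell_radius`; with the default shell the central
#' residue's relative SASA falls below the burial threshold, with
#' `shell_count = 0` it is fully exposed.
#'
#' @param spec A [fixture_spec()] with `kind = "burial"`.
#' @return PDB text (single string).
#' @export
make_burial_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$kind == "burial")
  central <- dplyr::bind_rows(
    fixture_atom("X", 1L, "ALA", "N", "N", -1.4, 0.4, -0.6),
    fixture_atom("X", 1L, "ALA", "CA", "C", 0.0, 0.0, -0.8),
    fixture_atom("X", 1L, "ALA", "C", "C", 0.8, 0.8, 0.2),
    fixture_atom("X", 1L, "ALA", "O", "O", 0.6, 2.0, 0.3),
    fixture_atom("X", 1L, "ALA", "CB", "C", 0.0, -1.0, 0.5))
  atoms <- central
  if (spec$shell_count > 0L) {
    pts <- sphere_points(spec$shell_count) * spec$shell_radius
    shell <- fixture_atom("S", 100L + seq_len(spec$shell_count), "ALA",
                          "CB", "C", pts[, 1], pts[, 2], pts[, 3])
    atoms <- dplyr::bind_rows(central, shell)
  }
  single_model_pdb_text(atoms)
}

#' Multi-model ensemble fixture with seeded coordinate jitter
#'
#' Replicates a base model `spec$n_models` times, adding isotropic Gaussian
#' jitter of standard deviation `spec$jitter_sd` to every coordinate, and
#' frames the models with MODEL/ENDMDL records. Identical specs (including
#' seed) give byte-identical text.
#'
#' @param spec A [fixture_spec()] with `kind = "ensemble"`.
#' @param base Single-model PDB text to replicate; defaults to the
#'   salt-bridge fixture at `spec$distance`.
#' @return Multi-model PDB text (single string).
#' @export
make_ensemble_fixture <- function(spec, base = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), spec$kind == "ensemble")
  if (is.null(base)) {
    base <- make_salt_bridge_fixture(
      fixture_spec("salt_bridge", distance = spec$distance))
  }
  lines <- strsplit(base, "\n", fixed = TRUE)[[1]]
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  n_atoms <- length(atom_lines)
  withr::with_seed(spec$seed, {
    blocks <- purrr::map(seq_len(spec$n_models), function(k) {
      jit <- matrix(stats::rnorm(3L * n_atoms, sd = spec$jitter_sd),
                    ncol = 3L)
      moved <- purrr::map_chr(seq_len(n_atoms), function(i) {
        l <- atom_lines[i]
        x <- as.numeric(substr(l, 31, 38)) + jit[i, 1]
        y <- as.numeric(substr(l, 39, 46)) + jit[i, 2]
        z <- as.numeric(substr(l, 47, 54)) + jit[i, 3]
        paste0(substr(l, 1, 30), sprintf("%8.3f%8.3f%8.3f", x, y, z),
               substr(l, 55, nchar(l)))
      })
      c(sprintf("MODEL     %4d", k), moved, "ENDMDL")
    })
    paste(c(unlist(blocks), "END"), collapse = "\n")
  })
}

#' Assignment-table fixture with an explicit dropped-nucleus set
#'
#' Generates a complete expected side-chain assignment table for the given
#' residues, removes exactly the requested (residue, nucleus) drop set, and
#' renders it as the simplified TSV dialect or as a minimal NMR-STAR
#' assigned-chemical-shift loop.
#'
#' @param spec A [fixture_spec()] with `kind = "assignments"` (`seed` fixes
#'   the synthetic shift values).
#' @param residues A tibble with columns `entity`, `resno`, `resid`.
#' @param drop A tibble with columns `entity`, `resno`, `atom`: entries to
#'   omit. May be empty.
#' @param format `"tsv"` or `"nmrstar"`.
#' @param expected Expected-nuclei table, see
#'   [expected_sidechain_nuclei()].
#' @return Text of the fixture (single string).
#' @export
make_assignment_fixture <- function(spec, residues,
                                    drop = NULL,
                                    format = c("tsv", "nmrstar"),
                                    expected = expected_sidechain_nuclei()) {
  stopifnot(inherits(spec, "fixture_spec"), spec$kind == "assignments")
  format <- match.arg(format)
  residues <- tibble::as_tibble(residues)
  full <- residues |>
    dplyr::inner_join(expected, by = "resid",
                      relationship = "many-to-many") |>
    dplyr::mutate(entity = as.character(.data$entity),
                  resno = as.integer(.data$resno))
  if (!is.null(drop) && nrow(drop) > 0L) {
    drop <- dplyr::mutate(tibble::as_tibble(drop),
                          entity = as.character(.data$entity),
                          resno = as.integer(.data$resno))
    full <- dplyr::anti_join(full, drop,
                             by = c("entity", "resno", "atom"))
  }
  full <- withr::with_seed(spec$seed, {
    dplyr::mutate(full,
                  shift = round(stats::runif(dplyr::n(), 0.5, 180), 3),
                  ambiguity = 1L)
  })
  if (format == "tsv") {
    header <- "entity\tresidue\tres_type\tatom\tshift\tambiguity"
    body <- sprintf("%s\t%d\t%s\t%s\t%.3f\t%d", full$entity, full$resno,
                    full$resid, full$atom, full$shift, full$ambiguity)
    paste(c(header, body), collapse = "\n")
  } else {
    tags <- paste0("      _Atom_chem_shift.",
                   c("ID", "Entity_ID", "Seq_ID", "Comp_ID", "Atom_ID",
                     "Val", "Ambiguity_code"))
    body <- sprintf("      %d %s %d %s %s %.3f %d",
                    seq_len(nrow(full)), full$entity, full$resno,
                    full$resid, full$atom, full$shift, full$ambiguity)
    paste(c("data_synthetic_shifts", "", "save_assigned_chemical_shifts",
            "   loop_", tags, body, "   stop_", "save_"),
          collapse = "\n")
  }
}
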