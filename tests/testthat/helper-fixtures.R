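# Shared fixture builders and independent brute-force oracles. The oracles
# re-derive detections from first principles (literal loops over atoms and
# the published chemistry definitions) so that the package's detectors can
# be checked against a second, independent code path.

write_fixture <- function(text) {
  f <- tempfile(fileext = ".pdb")
  writeLines(text, f)
  f
}

read_fixture <- function(text, ...) {
  read_multimodel_pdb(write_fixture(text), ...)
}

fixture_atom_row <- function(chain, resno, resid, atom, element, x, y, z) {
  tibble::tibble(model = 1L, chain = chain, resno = as.integer(resno),
                 icode = "", resid = resid, atom = atom, element = element,
                 altloc = "", occ = 1, x = x, y = y, z = z)
}

# A random cloud of complete charged side-chain groups (plus CA), for
# oracle-equivalence testing. Group atoms sit at fixed small offsets from a
# random residue anchor, so inter-residue distances straddle the cutoffs.
random_charged_model <- function(n_residues, seed, box = 14) {
  withr::with_seed(seed, {
    types <- sample(c("ASP", "GLU", "LYS", "ARG", "HIS"), n_residues,
                    replace = TRUE)
    offsets <- list(
      ASP = list(c("OD1", "O", 0.6, 0.8, 0), c("OD2", "O", 0.6, -0.8, 0)),
      GLU = list(c("OE1", "O", 0.6, 0.8, 0), c("OE2", "O", 0.6, -0.8, 0)),
      LYS = list(c("NZ", "N", 0.7, 0, 0)),
      ARG = list(c("NE", "N", 0.5, 0.9, 0), c("NH1", "N", 1.2, -0.4, 0.5),
                 c("NH2", "N", 1.2, -0.4, -0.5)),
      HIS = list(c("ND1", "N", 0.7, 0.7, 0), c("NE2", "N", 1.3, -0.4, 0)))
    purrr::map_dfr(seq_len(n_residues), function(i) {
      anchor <- stats::runif(3, 0, box)
      chain <- sample(c("A", "B"), 1L)
      rows <- purrr::map_dfr(offsets[[types[i]]], function(o) {
        fixture_atom_row(chain, i, types[i], o[1], o[2],
                         anchor[1] + as.numeric(o[3]),
                         anchor[2] + as.numeric(o[4]),
                         anchor[3] + as.numeric(o[5]))
      })
      dplyr::bind_rows(
        fixture_atom_row(chain, i, types[i], "CA", "C",
                         anchor[1] - 1.5, anchor[2], anchor[3]),
        rows)
    })
  })
}

# Random donors (Lys ammonium with three H) and acceptors (Gln OE1 plus a
# backbone O) for hydrogen-bond oracle testing.
random_hbond_model <- function(n_residues, seed, box = 10) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_residues), function(i) {
      anchor <- stats::runif(3, 0, box)
      chain <- sample(c("A", "B"), 1L)
      if (i %% 2L == 1L) {
        nz <- anchor
        hs <- purrr::map_dfr(1:3, function(k) {
          dir <- c(cos(2 * pi * k / 3), sin(2 * pi * k / 3), 0.3)
          dir <- dir / sqrt(sum(dir^2))
          fixture_atom_row(chain, i, "LYS", paste0("HZ", k), "H",
                           nz[1] + dir[1], nz[2] + dir[2], nz[3] + dir[3])
        })
        dplyr::bind_rows(
          fixture_atom_row(chain, i, "LYS", "NZ", "N", nz[1], nz[2], nz[3]),
          hs)
      } else {
        dplyr::bind_rows(
          fixture_atom_row(chain, i, "GLN", "OE1", "O",
                           anchor[1], anchor[2], anchor[3]),
          fixture_atom_row(chain, i, "GLN", "O", "O",
                           anchor[1] + 1.1, anchor[2] - 0.8, anchor[3]))
      }
    })
  })
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

coords_of <- function(model, i) c(model$x[i], model$y[i], model$z[i])

# Brute-force salt-bridge oracle, atom_pair mode: every (positive N atom,
# negative O atom) pair from different residues within the cutoff.
oracle_salt_bridges_atom_pair <- function(model, cutoff = 4.0) {
  group_atoms <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), LYS = "NZ",
    ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))
  polarity <- c(ASP = "negative", GLU = "negative", LYS = "positive",
                ARG = "positive", HIS = "positive")
  out <- list()
  for (i in seq_len(nrow(model))) {
    for (j in seq_len(nrow(model))) {
      ri <- model$resid[i]; rj <- model$resid[j]
      if (!(ri %in% names(polarity)) || !(rj %in% names(polarity))) next
      if (polarity[ri] != "positive" || polarity[rj] != "negative") next
      if (!(model$atom[i] %in% group_atoms[[ri]])) next
      if (!(model$atom[j] %in% group_atoms[[rj]])) next
      same <- model$chain[i] == model$chain[j] &&
        model$resno[i] == model$resno[j]
      if (same) next
      d <- dist3(coords_of(model, i), coords_of(model, j))
      if (d <= cutoff) {
        out[[length(out) + 1L]] <- tibble::tibble(
          resno_a = model$resno[i], atom_a = model$atom[i],
          resno_b = model$resno[j], atom_b = model$atom[j],
          distance = d)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(resno_a = integer(), atom_a = character(),
                          resno_b = integer(), atom_b = character(),
                          distance = double()))
  }
  dplyr::arrange(dplyr::bind_rows(out), resno_a, resno_b, atom_a, atom_b)
}

# Brute-force group-center oracle.
oracle_salt_bridges_group_center <- function(model, cutoff = 4.0) {
  group_atoms <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), LYS = "NZ",
    ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))
  polarity <- c(ASP = "negative", GLU = "negative", LYS = "positive",
                ARG = "positive", HIS = "positive")
  res <- dplyr::distinct(model[model$resid %in% names(polarity), ],
                         chain, resno, resid)
  centers <- purrr::pmap_dfr(res, function(chain, resno, resid) {
    sel <- model$chain == chain & model$resno == resno &
      model$atom %in% group_atoms[[resid]]
    tibble::tibble(chain = chain, resno = resno, resid = resid,
                   pol = polarity[[resid]],
                   cx = mean(model$x[sel]), cy = mean(model$y[sel]),
                   cz = mean(model$z[sel]))
  })
  out <- list()
  for (i in seq_len(nrow(centers))) {
    for (j in seq_len(nrow(centers))) {
      if (centers$pol[i] != "positive" || centers$pol[j] != "negative") next
      d <- dist3(c(centers$cx[i], centers$cy[i], centers$cz[i]),
                 c(centers$cx[j], centers$cy[j], centers$cz[j]))
      if (d <= cutoff) {
        out[[length(out) + 1L]] <- tibble::tibble(
          resno_a = centers$resno[i], resno_b = centers$resno[j],
          distance = d)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(resno_a = integer(), resno_b = integer(),
                          distance = double()))
  }
  dplyr::arrange(dplyr::bind_rows(out), resno_a, resno_b)
}

# Brute-force hydrogen-bond oracle: triple loop over donor heavy atoms,
# their bound hydrogens and acceptor atoms.
oracle_hbonds <- function(model, da_cut = 3.0, ang_cut = 30) {
  donors <- c(LYS = "NZ")
  acceptors <- list(GLN = c("OE1", "O"), LYS = "O")
  out <- list()
  for (i in seq_len(nrow(model))) {
    if (!(model$resid[i] %in% names(donors))) next
    if (model$atom[i] != donors[[model$resid[i]]]) next
    dpos <- coords_of(model, i)
    for (k in seq_len(nrow(model))) {
      if (model$element[k] != "H") next
      if (model$chain[k] != model$chain[i] ||
          model$resno[k] != model$resno[i]) next
      hpos <- coords_of(model, k)
      if (dist3(dpos, hpos) >= 1.3) next
      for (j in seq_len(nrow(model))) {
        if (!(model$resid[j] %in% names(acceptors))) next
        if (!(model$atom[j] %in% acceptors[[model$resid[j]]])) next
        if (model$chain[j] == model$chain[i] &&
            model$resno[j] == model$resno[i]) next
        apos <- coords_of(model, j)
        dda <- dist3(dpos, apos)
        v1 <- apos - dpos; v2 <- hpos - dpos
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (dda <= da_cut && ang <= ang_cut) {
          out[[length(out) + 1L]] <- tibble::tibble(
            resno_d = model$resno[i], hydrogen = model$atom[k],
            resno_a = model$resno[j], acceptor = model$atom[j],
            d_da = dda, angle = ang)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(resno_d = integer(), hydrogen = character(),
                          resno_a = integer(), acceptor = character(),
                          d_da = double(), angle = double()))
  }
  dplyr::arrange(dplyr::bind_rows(out), resno_d, resno_a, hydrogen, acceptor)
}
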