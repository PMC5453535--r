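# Geometric detection of salt bridges and side-chain hydrogen bonds.
#
# Criteria (all comparisons inclusive):
#   salt bridge    : oppositely charged side-chain groups within 4.0 A,
#                    either group-center to group-center or per N/O atom pair
#   hydrogen bond  : d(D,A) <= 3.0 A and angle at D between the D->H and
#                    D->A rays (the "ADH" angle of a near-linear bond)
#                    <= 30 degrees, H covalently bound to D (< 1.3 A, same
#                    residue)

#' Detection configuration
#'
#' Bundles every geometric cutoff and mode switch used by the detectors.
#' Defaults are the criteria of the published SMN ensemble analysis:
#' 4.0 Angstrom salt-bridge cutoff, 3.0 Angstrom donor-acceptor cutoff and
#' 30 degree ADH-angle cutoff, all inclusive.
#'
#' @param sb_cutoff Salt-bridge distance cutoff in Angstroms.
#' @param hb_da_cutoff Hydrogen-bond donor-acceptor distance cutoff
#'   (Angstroms).
#' @param hb_angle_cutoff Hydrogen-bond ADH angle cutoff (degrees).
#' @param sb_mode `"atom_pair"` (default) emits one bridge per qualifying
#'   negative-O / positive-N atom pair; `"group_center"` emits one bridge
#'   per group pair, measured between the unweighted geometric centers of
#'   the charged groups.
#' @param hb_acceptor_scope `"sidechain_plus_backbone_O"` (default) also
#'   admits backbone carbonyl oxygens as acceptors; `"sidechain_only"`
#'   restricts acceptors to side-chain atoms.
#' @param sd Standard-deviation convention for ensemble statistics:
#'   `"population"` (divisor n, default) or `"sample"` (divisor n - 1).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(sb_cutoff = 4.0,
                             hb_da_cutoff = 3.0,
                             hb_angle_cutoff = 30,
                             sb_mode = c("atom_pair", "group_center"),
                             hb_acceptor_scope = c("sidechain_plus_backbone_O",
                                                   "sidechain_only"),
                             sd = c("population", "sample")) {
  stopifnot(sb_cutoff > 0, hb_da_cutoff > 0, hb_angle_cutoff > 0)
  structure(
    list(sb_cutoff = sb_cutoff,
         hb_da_cutoff = hb_da_cutoff,
         hb_angle_cutoff = hb_angle_cutoff,
         sb_mode = match.arg(sb_mode),
         hb_acceptor_scope = match.arg(hb_acceptor_scope),
         sd = match.arg(sd)),
    class = "detection_config")
}

sd_fun <- function(config) {
  if (config$sd == "sample") {
    function(x) if (length(x) > 1L) stats::sd(x) else 0
  } else {
    function(x) sqrt(mean((x - mean(x))^2))
  }
}

res_key <- function(chain, resno, icode) paste0(chain, ":", resno, icode)

#' Charged side-chain groups of a model
#'
#' Identifies the charged groups of the titratable residues: Asp
#' (OD1/OD2, negative), Glu (OE1/OE2, negative), Lys (NZ, positive), Arg
#' (NE/NH1/NH2, positive) and His (ND1/NE2, treated as positive). The group
#' center is the unweighted mean of the member atoms actually present;
#' residues with every member atom missing are skipped with a warning.
#'
#' @param model A single-model atom tibble.
#' @return A tibble with one row per charged group: residue identity,
#'   `polarity`, member atom table (`atoms`, a list column with columns
#'   `atom`, `x`, `y`, `z`), and center coordinates `cx`, `cy`, `cz`.
#' @export
charged_groups <- function(model) {
  model <- tibble::as_tibble(model)
  tab <- charged_group_table()
  cand <- dplyr::distinct(
    dplyr::filter(model, .data$resid %in% tab$resid),
    .data$chain, .data$resno, .data$icode, .data$resid)
  if (nrow(cand) == 0L) return(empty_group_tbl())

  out <- purrr::pmap_dfr(cand, function(chain, resno, icode, resid) {
    members <- tab$member_atoms[[match(resid, tab$resid)]]
    at <- select_atoms(model, chain, resno, members, icode = icode)
    if (nrow(at) == 0L) {
      warning("charged group atoms all missing for ",
              res_key(chain, resno, icode), " ", resid)
      return(NULL)
    }
    tibble::tibble(
      chain = chain, resno = resno, icode = icode, resid = resid,
      polarity = tab$polarity[match(resid, tab$resid)],
      atoms = list(at[, c("atom", "x", "y", "z")]),
      cx = mean(at$x), cy = mean(at$y), cz = mean(at$z))
  })
  if (is.null(out) || nrow(out) == 0L) empty_group_tbl() else out
}

empty_group_tbl <- function() {
  tibble::tibble(chain = character(), resno = integer(), icode = character(),
                 resid = character(), polarity = character(),
                 atoms = list(), cx = double(), cy = double(), cz = double())
}

empty_sb_tbl <- function() {
  tibble::tibble(model = integer(),
                 chain_a = character(), resno_a = integer(),
                 icode_a = character(), resid_a = character(),
                 atom_a = character(),
                 chain_b = character(), resno_b = integer(),
                 icode_b = character(), resid_b = character(),
                 atom_b = character(),
                 distance = double(), mode = character(),
                 scope = character())
}

#' Detect salt bridges in one model
#'
#' In `group_center` mode a bridge is one opposite-polarity group pair whose
#' center-center distance is at or below the cutoff; in `atom_pair` mode a
#' bridge is one (positive N, negative O) atom pair at or below the cutoff.
#' Pairs within one residue are never emitted. Partner `a` is the positive
#' side, partner `b` the negative side.
#'
#' @param model A single-model atom tibble.
#' @param config A [detection_config()].
#' @return A tibble of detected bridges with both partners' identities, the
#'   measured `distance`, the detection `mode` and the `scope`
#'   (`"intramolecular"` or `"intermolecular"`).
#' @export
detect_salt_bridges <- function(model, config = detection_config()) {
  model <- tibble::as_tibble(model)
  groups <- charged_groups(model)
  model_index <- if (nrow(model) > 0L && "model" %in% names(model)) {
    model$model[1L]
  } else NA_integer_
  pos <- dplyr::filter(groups, .data$polarity == "positive")
  neg <- dplyr::filter(groups, .data$polarity == "negative")
  if (nrow(pos) == 0L || nrow(neg) == 0L) return(empty_sb_tbl())

  rows <- list()
  for (i in seq_len(nrow(pos))) {
    for (j in seq_len(nrow(neg))) {
      same_res <- pos$chain[i] == neg$chain[j] &&
        pos$resno[i] == neg$resno[j] && pos$icode[i] == neg$icode[j]
      if (same_res) next
      if (config$sb_mode == "group_center") {
        d <- sqrt((pos$cx[i] - neg$cx[j])^2 + (pos$cy[i] - neg$cy[j])^2 +
                    (pos$cz[i] - neg$cz[j])^2)
        if (d <= config$sb_cutoff) {
          rows[[length(rows) + 1L]] <- sb_row(model_index, pos[i, ], neg[j, ],
                                              NA_character_, NA_character_,
                                              d, "group_center")
        }
      } else {
        pa <- pos$atoms[[i]]
        na <- neg$atoms[[j]]
        for (u in seq_len(nrow(pa))) {
          for (v in seq_len(nrow(na))) {
            d <- sqrt((pa$x[u] - na$x[v])^2 + (pa$y[u] - na$y[v])^2 +
                        (pa$z[u] - na$z[v])^2)
            if (d <= config$sb_cutoff) {
              rows[[length(rows) + 1L]] <-
                sb_row(model_index, pos[i, ], neg[j, ],
                       pa$atom[u], na$atom[v], d, "atom_pair")
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_sb_tbl())
  dplyr::bind_rows(rows)
}

sb_row <- function(model_index, p, n, atom_a, atom_b, d, mode) {
  tibble::tibble(
    model = model_index,
    chain_a = p$chain, resno_a = p$resno, icode_a = p$icode,
    resid_a = p$resid, atom_a = atom_a,
    chain_b = n$chain, resno_b = n$resno, icode_b = n$icode,
    resid_b = n$resid, atom_b = atom_b,
    distance = d, mode = mode,
    scope = ifelse(p$chain == n$chain, "intramolecular", "intermolecular"))
}

#' Hydrogen-bond donor and acceptor inventory of a model
#'
#' Donors are side-chain heteroatoms with at least one covalently bound
#' hydrogen (resolved geometrically: same residue, D-H distance below
#' 1.3 Angstroms); each (donor, hydrogen) pair is one entry, so a lysine
#' ammonium group contributes three. Acceptors are side-chain O/N/S
#' acceptor atoms (His ring nitrogens only when unprotonated) plus,
#' depending on `hb_acceptor_scope`, backbone carbonyl oxygens. Donor heavy
#' atoms with no resolvable hydrogen are skipped with a warning.
#'
#' @inheritParams detect_salt_bridges
#' @return A list with tibbles `donors` (columns `chain`, `resno`, `icode`,
#'   `resid`, `donor_atom`, `hydrogen_atom`, coordinates of both) and
#'   `acceptors` (residue identity, `acceptor_atom`, coordinates,
#'   `is_backbone`).
#' @export
donor_acceptor_inventory <- function(model, config = detection_config()) {
  model <- tibble::as_tibble(model)
  hydrogens <- dplyr::filter(model, .data$element %in% c("H", "D"))

  bound_h <- function(row) {
    hh <- dplyr::filter(hydrogens, .data$chain == row$chain,
                        .data$resno == row$resno, .data$icode == row$icode)
    if (nrow(hh) == 0L) return(hh)
    d <- sqrt((hh$x - row$x)^2 + (hh$y - row$y)^2 + (hh$z - row$z)^2)
    hh[d < 1.3, , drop = FALSE]
  }

  don_tab <- donor_atom_table()
  don_heavy <- dplyr::inner_join(model, don_tab, by = c("resid", "atom"))
  donors <- purrr::map_dfr(seq_len(nrow(don_heavy)), function(i) {
    row <- don_heavy[i, ]
    hh <- bound_h(row)
    if (nrow(hh) == 0L) {
      warning("donor ", row$atom, " of ",
              res_key(row$chain, row$resno, row$icode), " ", row$resid,
              " has no bound hydrogen; skipped")
      return(NULL)
    }
    tibble::tibble(
      chain = row$chain, resno = row$resno, icode = row$icode,
      resid = row$resid, donor_atom = row$atom,
      dx = row$x, dy = row$y, dz = row$z,
      hydrogen_atom = hh$atom, hx = hh$x, hy = hh$y, hz = hh$z)
  })
  if (is.null(donors) || nrow(donors) == 0L) {
    donors <- tibble::tibble(chain = character(), resno = integer(),
                             icode = character(), resid = character(),
                             donor_atom = character(), dx = double(),
                             dy = double(), dz = double(),
                             hydrogen_atom = character(), hx = double(),
                             hy = double(), hz = double())
  }

  acc_tab <- acceptor_atom_table()
  acc <- dplyr::inner_join(model, acc_tab, by = c("resid", "atom"))
  if (nrow(acc) > 0L) {
    # His ring nitrogens accept only when unprotonated
    keep <- purrr::map_lgl(seq_len(nrow(acc)), function(i) {
      row <- acc[i, ]
      if (row$resid != "HIS") return(TRUE)
      nrow(bound_h(row)) == 0L
    })
    acc <- acc[keep, , drop = FALSE]
  }
  acc <- dplyr::mutate(acc, is_backbone = FALSE)
  if (config$hb_acceptor_scope == "sidechain_plus_backbone_O") {
    bb <- model |>
      dplyr::filter(.data$atom == "O") |>
      dplyr::mutate(is_backbone = TRUE)
    acc <- dplyr::bind_rows(acc, bb)
  }
  acceptors <- tibble::tibble(
    chain = acc$chain, resno = acc$resno, icode = acc$icode,
    resid = acc$resid, acceptor_atom = acc$atom,
    ax = acc$x, ay = acc$y, az = acc$z, is_backbone = acc$is_backbone)

  list(donors = donors, acceptors = acceptors)
}

empty_hb_tbl <- function() {
  tibble::tibble(model = integer(),
                 chain_d = character(), resno_d = integer(),
                 icode_d = character(), resid_d = character(),
                 donor_atom = character(), hydrogen_atom = character(),
                 chain_a = character(), resno_a = integer(),
                 icode_a = character(), resid_a = character(),
                 acceptor_atom = character(), acceptor_is_backbone = logical(),
                 d_da = double(), d_ha = double(), angle_adh = double(),
                 scope = character())
}

#' Detect side-chain hydrogen bonds in one model
#'
#' For every donor (D, H) pair and every acceptor A in a different residue,
#' a hydrogen bond is emitted iff the donor-acceptor distance and the ADH
#' angle (measured at D, between the D to A and D to H rays) are at or below
#' their cutoffs. The hydrogen-acceptor distance is reported but is not a
#' criterion.
#'
#' @inheritParams detect_salt_bridges
#' @return A tibble of detected bonds with donor, hydrogen and acceptor
#'   identities, `d_da`, `d_ha`, `angle_adh` and `scope`.
#' @export
detect_hydrogen_bonds <- function(model, config = detection_config()) {
  model <- tibble::as_tibble(model)
  inv <- donor_acceptor_inventory(model, config)
  don <- inv$donors
  acc <- inv$acceptors
  model_index <- if (nrow(model) > 0L && "model" %in% names(model)) {
    model$model[1L]
  } else NA_integer_
  if (nrow(don) == 0L || nrow(acc) == 0L) return(empty_hb_tbl())

  rows <- list()
  for (i in seq_len(nrow(don))) {
    for (j in seq_len(nrow(acc))) {
      if (don$chain[i] == acc$chain[j] && don$resno[i] == acc$resno[j] &&
          don$icode[i] == acc$icode[j]) next
      geom <- hbond_geometry(
        c(don$dx[i], don$dy[i], don$dz[i]),
        c(don$hx[i], don$hy[i], don$hz[i]),
        c(acc$ax[j], acc$ay[j], acc$az[j]))
      if (geom$d_da <= config$hb_da_cutoff &&
          geom$angle_adh <= config$hb_angle_cutoff) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = model_index,
          chain_d = don$chain[i], resno_d = don$resno[i],
          icode_d = don$icode[i], resid_d = don$resid[i],
          donor_atom = don$donor_atom[i],
          hydrogen_atom = don$hydrogen_atom[i],
          chain_a = acc$chain[j], resno_a = acc$resno[j],
          icode_a = acc$icode[j], resid_a = acc$resid[j],
          acceptor_atom = acc$acceptor_atom[j],
          acceptor_is_backbone = acc$is_backbone[j],
          d_da = geom$d_da, d_ha = geom$d_ha, angle_adh = geom$angle_adh,
          scope = ifelse(don$chain[i] == acc$chain[j],
                         "intramolecular", "intermolecular"))
      }
    }
  }
  if (length(rows) == 0L) return(empty_hb_tbl())
  dplyr::bind_rows(rows)
}

#' Hydrogen-bond geometry from three coordinates
#'
#' @param d,h,a Numeric 3-vectors: donor, hydrogen, acceptor coordinates.
#' @return A list with `d_da`, `d_ha` (Angstroms) and `angle_adh` (degrees,
#'   at the donor vertex between the rays towards A and towards H).
#' @export
hbond_geometry <- function(d, h, a) {
  v_da <- a - d
  v_dh <- h - d
  d_da <- sqrt(sum(v_da^2))
  d_ha <- sqrt(sum((a - h)^2))
  cosv <- sum(v_da * v_dh) / (d_da * sqrt(sum(v_dh^2)))
  cosv <- min(1, max(-1, cosv))
  list(d_da = d_da, d_ha = d_ha, angle_adh = acos(cosv) * 180 / pi)
}

#' Do a distance/angle pair satisfy the hydrogen-bond criteria?
#'
#' @param d_da Donor-acceptor distance (Angstroms).
#' @param angle_adh ADH angle at the donor (degrees).
#' @param config A [detection_config()].
#' @return Logical vector.
#' @export
hb_criteria_met <- function(d_da, angle_adh, config = detection_config()) {
  d_da <= config$hb_da_cutoff & angle_adh <= config$hb_angle_cutoff
}

#' Classify an interaction table by chain scope
#'
#' @param interactions A tibble with `chain_a` and one of `chain_b` /
#'   `chain_d` (salt-bridge or hydrogen-bond table).
#' @return The input with its `scope` column (re)computed:
#'   `"intermolecular"` iff the two chains differ.
#' @export
classify_contact_scope <- function(interactions) {
  other <- if ("chain_b" %in% names(interactions)) "chain_b" else "chain_d"
  dplyr::mutate(
    interactions,
    scope = ifelse(.data$chain_a == .data[[other]],
                   "intramolecular", "intermolecular"))
}

parse_selector <- function(sel) {
  if (is.character(sel) && length(sel) == 1L) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("selector must be \"chain:resno:atom\", got: ", sel)
    }
    list(chain = parts[1L], resno = as.integer(parts[2L]), atom = parts[3L])
  } else if (is.list(sel)) {
    stopifnot(all(c("chain", "resno", "atom") %in% names(sel)))
    list(chain = as.character(sel$chain), resno = as.integer(sel$resno),
         atom = as.character(sel$atom))
  } else {
    stop("unsupported atom selector")
  }
}

select_one_atom <- function(model, sel) {
  hit <- select_atoms(model, sel$chain, sel$resno, sel$atom)
  if (nrow(hit) > 1L) {
    stop("selector ", sel$chain, ":", sel$resno, ":", sel$atom,
         " matches ", nrow(hit), " atoms")
  }
  hit
}

#' Distance between two named atoms across an ensemble
#'
#' Measures one distance per model between two atoms given as
#' `"chain:resno:atom"` selectors (or lists with those fields). Models in
#' which either atom is missing are skipped with a warning; a selector
#' matching more than one atom in a model is an error.
#'
#' @param ensemble An ensemble atom table.
#' @param a,b Atom selectors.
#' @return A tibble of class `distance_series` with columns `model` and
#'   `distance`; `glance()` yields the mean and standard deviation.
#' @param config A [detection_config()] (used for the standard-deviation
#'   convention).
#' @export
atom_pair_distance_series <- function(ensemble, a, b,
                                      config = detection_config()) {
  sa <- parse_selector(a)
  sb <- parse_selector(b)
  out <- purrr::map_dfr(sort(unique(ensemble$model)), function(k) {
    m <- get_model(ensemble, k)
    at_a <- select_one_atom(m, sa)
    at_b <- select_one_atom(m, sb)
    if (nrow(at_a) == 0L || nrow(at_b) == 0L) {
      warning("model ", k, ": selector atom missing; model skipped")
      return(NULL)
    }
    tibble::tibble(
      model = k,
      distance = sqrt((at_a$x - at_b$x)^2 + (at_a$y - at_b$y)^2 +
                        (at_a$z - at_b$z)^2))
  })
  structure(out, class = c("distance_series", class(out)),
            pair = paste(sa$chain, sa$resno, sa$atom, "-",
                         sb$chain, sb$resno, sb$atom),
            sd_type = config$sd)
}

#' @method glance distance_series
#' @export
glance.distance_series <- function(x, ...) {
  f <- sd_fun(detection_config(sd = attr(x, "sd_type") %||% "population"))
  tibble::tibble(pair = attr(x, "pair"),
                 n_models = nrow(x),
                 distance_mean = mean(x$distance),
                 distance_std = f(x$distance))
}

#' @method autoplot distance_series
#' @export
autoplot.distance_series <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model, y = .data$distance)) +
    ggplot2::geom_hline(yintercept = g$distance_mean, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = g$distance_mean - g$distance_std,
                   ymax = g$distance_mean + g$distance_std),
      fill = "grey85") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "model", y = "distance (Å)",
                  title = attr(object, "pair")) +
    ggplot2::theme_minimal()
}
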