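# Ensemble-level aggregation of per-model detections.

#' Summarize detected interactions across an ensemble
#'
#' Runs the requested detector on every model and pools the detections per
#' partner pair. Pair identity is the residue pair plus, in `atom_pair`
#' salt-bridge mode and for hydrogen bonds, the participating atom names, so
#' a census like "four atom-pair bridges between two residues" and one like
#' "fifteen models with the same residue-pair bridge" are both expressible.
#' Distance statistics are computed over the detected instances only; pairs
#' never detected are omitted.
#'
#' @param ensemble An ensemble atom table.
#' @param config A [detection_config()].
#' @param kind `"salt_bridge"` or `"hydrogen_bond"`.
#' @return A tibble of class `interaction_summary`: partner identities,
#'   `n_models_detected`, `n_instances`, `model_indices` (list column),
#'   `distance_mean`, `distance_std`, `scope`.
#' @export
summarize_interactions <- function(ensemble, config = detection_config(),
                                   kind = c("salt_bridge", "hydrogen_bond")) {
  kind <- match.arg(kind)
  detections <- detect_in_ensemble(ensemble, config, kind)
  sdf <- sd_fun(config)
  if (nrow(detections) == 0L) {
    return(structure(detections, class = c("interaction_summary",
                                           class(detections))))
  }

  if (kind == "salt_bridge") {
    keys <- c("chain_a", "resno_a", "icode_a", "resid_a",
              "chain_b", "resno_b", "icode_b", "resid_b")
    if (config$sb_mode == "atom_pair") keys <- c(keys, "atom_a", "atom_b")
    dist_col <- "distance"
  } else {
    keys <- c("chain_d", "resno_d", "icode_d", "resid_d", "donor_atom",
              "hydrogen_atom", "chain_a", "resno_a", "icode_a", "resid_a",
              "acceptor_atom")
    dist_col <- "d_da"
  }

  out <- detections |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_models_detected = length(unique(.data$model)),
      n_instances = dplyr::n(),
      model_indices = list(sort(unique(.data$model))),
      distance_mean = mean(.data[[dist_col]]),
      distance_std = sdf(.data[[dist_col]]),
      scope = .data$scope[1L],
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_models_detected))
  structure(out, class = c("interaction_summary", class(out)),
            kind = kind, config = config)
}

detect_in_ensemble <- function(ensemble, config, kind) {
  detector <- if (kind == "salt_bridge") detect_salt_bridges
  else detect_hydrogen_bonds
  purrr::map_dfr(sort(unique(ensemble$model)),
                 function(k) detector(get_model(ensemble, k), config))
}

#' @method glance interaction_summary
#' @export
glance.interaction_summary <- function(x, ...) {
  tibble::tibble(kind = attr(x, "kind") %||% NA_character_,
                 n_pairs = nrow(x),
                 n_instances = if (nrow(x)) sum(x$n_instances) else 0L,
                 n_intermolecular = if (nrow(x)) {
                   sum(x$scope == "intermolecular")
                 } else 0L)
}

#' Per-model geometry of one donor/hydrogen/acceptor triple
#'
#' Measures the hydrogen-bond geometry (donor-acceptor distance,
#' hydrogen-acceptor distance, ADH angle) of a fixed atom triple in every
#' model, whether or not the bond criteria hold, plus the mean and standard
#' deviation over all models. This is the "distribution row" companion to a
#' single-model detection.
#'
#' @param ensemble An ensemble atom table.
#' @param donor,acceptor Atom selectors (`"chain:resno:atom"`).
#' @param hydrogen Hydrogen atom name within the donor residue.
#' @param config A [detection_config()] (criteria and sd convention).
#' @return A tibble of class `hbond_pair_profile` with one row per model
#'   (`d_da`, `d_ha`, `angle_adh`, `detected`); `glance()` returns the
#'   distribution row.
#' @export
summarize_hbond_pair <- function(ensemble, donor, hydrogen, acceptor,
                                 config = detection_config()) {
  sd_ <- parse_selector(donor)
  sa_ <- parse_selector(acceptor)
  out <- purrr::map_dfr(sort(unique(ensemble$model)), function(k) {
    m <- get_model(ensemble, k)
    at_d <- select_one_atom(m, sd_)
    at_h <- select_atoms(m, sd_$chain, sd_$resno, hydrogen)
    at_a <- select_one_atom(m, sa_)
    if (nrow(at_d) == 0L || nrow(at_h) == 0L || nrow(at_a) == 0L) {
      warning("model ", k, ": atom of the requested triple missing; skipped")
      return(NULL)
    }
    if (nrow(at_h) > 1L) stop("hydrogen name matches several atoms")
    geom <- hbond_geometry(c(at_d$x, at_d$y, at_d$z),
                           c(at_h$x, at_h$y, at_h$z),
                           c(at_a$x, at_a$y, at_a$z))
    tibble::tibble(model = k, d_da = geom$d_da, d_ha = geom$d_ha,
                   angle_adh = geom$angle_adh,
                   detected = hb_criteria_met(geom$d_da, geom$angle_adh,
                                              config))
  })
  structure(out, class = c("hbond_pair_profile", class(out)),
            donor = donor, hydrogen = hydrogen, acceptor = acceptor,
            sd_type = config$sd)
}

#' @method glance hbond_pair_profile
#' @export
glance.hbond_pair_profile <- function(x, ...) {
  f <- sd_fun(detection_config(sd = attr(x, "sd_type") %||% "population"))
  tibble::tibble(
    donor = attr(x, "donor"), hydrogen = attr(x, "hydrogen"),
    acceptor = attr(x, "acceptor"),
    n_models = nrow(x), n_detected = sum(x$detected),
    d_da_mean = mean(x$d_da), d_da_std = f(x$d_da),
    d_ha_mean = mean(x$d_ha), d_ha_std = f(x$d_ha),
    angle_adh_mean = mean(x$angle_adh), angle_adh_std = f(x$angle_adh))
}

#' @method autoplot hbond_pair_profile
#' @export
autoplot.hbond_pair_profile <- function(object, config = detection_config(),
                                        ...) {
  dat <- tidyr::pivot_longer(tibble::as_tibble(object),
                             c("d_da", "angle_adh"),
                             names_to = "quantity", values_to = "value")
  cuts <- tibble::tibble(quantity = c("d_da", "angle_adh"),
                         cut = c(config$hb_da_cutoff,
                                 config$hb_angle_cutoff))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$detected)) +
    ggplot2::geom_hline(data = cuts, ggplot2::aes(yintercept = .data$cut),
                        linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "model", y = NULL) +
    ggplot2::theme_minimal()
}
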