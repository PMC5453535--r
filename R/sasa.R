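# Shrake-Rupley solvent accessible surface area.
#
# Each atom's accessible area is estimated by placing a deterministic
# golden-section spiral of test points on the sphere of radius
# r_vdw + probe and counting the fraction not occluded by any neighbouring
# atom's expanded sphere. Hydrogens are excluded from both the surface and
# the occlusion set by default so that NMR models (with H) and X-ray models
# (without) are comparable.

#' Deterministic unit-sphere quadrature points
#'
#' Golden-section spiral: near-uniform coverage with no random seed.
#'
#' @param n Number of points.
#' @return An `n` by 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_radius <- function(element, radii, unknown = c("default", "error")) {
  unknown <- match.arg(unknown)
  r <- unname(radii[element])
  miss <- is.na(r)
  if (any(miss)) {
    if (unknown == "error") {
      stop("no van der Waals radius for element(s): ",
           paste(unique(element[miss]), collapse = ", "))
    }
    warning("default radius used for element(s): ",
            paste(unique(element[miss]), collapse = ", "))
    r[miss] <- unname(radii["*"])
  }
  r
}

#' Per-atom solvent accessible surface area of one model
#'
#' @param model A single-model atom tibble.
#' @param probe_radius Solvent probe radius in Angstroms (water: 1.4).
#' @param n_sphere_points Quadrature points per atom.
#' @param radii Named element-radius vector, see [vdw_radii()].
#' @param include_hydrogens Include hydrogens in the surface and occlusion
#'   sets (default `FALSE`).
#' @param unknown_element `"default"` (fall back to the `"*"` radius with a
#'   warning) or `"error"`.
#' @return The model tibble (heavy atoms only unless
#'   `include_hydrogens = TRUE`) with an added `sasa` column in squared
#'   Angstroms.
#' @export
atom_sasa <- function(model, probe_radius = 1.4, n_sphere_points = 960,
                      radii = vdw_radii(), include_hydrogens = FALSE,
                      unknown_element = c("default", "error")) {
  model <- tibble::as_tibble(model)
  if (!include_hydrogens) {
    model <- dplyr::filter(model, !.data$element %in% c("H", "D"))
  }
  n <- nrow(model)
  if (n == 0L) return(dplyr::mutate(model, sasa = double()))
  pts <- sphere_points(n_sphere_points)
  xyz <- as.matrix(model[, c("x", "y", "z")])
  rad <- atom_radius(model$element, radii, unknown_element) + probe_radius

  sasa <- vapply(seq_len(n), function(i) {
    ri <- rad[i]
    # neighbour prefilter: spheres that can intersect atom i's test sphere
    dx <- xyz[, 1] - xyz[i, 1]
    dy <- xyz[, 2] - xyz[i, 2]
    dz <- xyz[, 3] - xyz[i, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    nb <- which(d2 < (ri + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0L) return(4 * pi * ri^2)
    cloud <- sweep(pts * ri, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- (cloud[accessible, 1] - xyz[j, 1])^2 +
        (cloud[accessible, 2] - xyz[j, 2])^2 +
        (cloud[accessible, 3] - xyz[j, 3])^2
      accessible[accessible] <- dj2 > rad[j]^2
    }
    4 * pi * ri^2 * sum(accessible) / n_sphere_points
  }, numeric(1))

  dplyr::mutate(model, sasa = sasa)
}

#' Per-residue SASA profile of an ensemble
#'
#' Sums member-atom SASA per residue in every model, then aggregates across
#' models: mean, standard deviation, intrinsic (standard reference) SASA and
#' the relative ratio mean / intrinsic.
#'
#' @param ensemble An ensemble atom table.
#' @param table Intrinsic reference table, see [intrinsic_sasa()].
#' @param sd `"population"` (default) or `"sample"` standard deviation.
#' @inheritParams atom_sasa
#' @return A tibble of class `sasa_profile` with columns `chain`, `resno`,
#'   `icode`, `resid`, `n_models`, `sasa_mean`, `sasa_std`,
#'   `sasa_intrinsic`, `sasa_ratio`.
#' @export
residue_sasa_profile <- function(ensemble, table = intrinsic_sasa(),
                                 probe_radius = 1.4, n_sphere_points = 960,
                                 radii = vdw_radii(),
                                 include_hydrogens = FALSE,
                                 sd = c("population", "sample")) {
  sd <- match.arg(sd)
  stopifnot(nrow(ensemble) > 0L)
  missing_types <- setdiff(unique(ensemble$resid), table$resid)
  if (length(missing_types) > 0L) {
    offenders <- ensemble |>
      dplyr::filter(.data$resid %in% missing_types) |>
      dplyr::distinct(.data$chain, .data$resno, .data$resid)
    stop("no intrinsic SASA value for residue(s): ",
         paste(paste0(offenders$chain, offenders$resno, offenders$resid),
               collapse = ", "))
  }
  sdf <- sd_fun(detection_config(sd = sd))

  per_model <- purrr::map_dfr(sort(unique(ensemble$model)), function(k) {
    atom_sasa(get_model(ensemble, k), probe_radius = probe_radius,
              n_sphere_points = n_sphere_points, radii = radii,
              include_hydrogens = include_hydrogens) |>
      dplyr::group_by(.data$model, .data$chain, .data$resno, .data$icode,
                      .data$resid) |>
      dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop")
  })

  out <- per_model |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$resid) |>
    dplyr::summarise(n_models = dplyr::n(),
                     sasa_mean = mean(.data$sasa),
                     sasa_std = sdf(.data$sasa),
                     .groups = "drop") |>
    dplyr::left_join(table, by = "resid") |>
    dplyr::mutate(sasa_ratio = .data$sasa_mean / .data$sasa_intrinsic) |>
    dplyr::arrange(.data$chain, .data$resno, .data$icode)
  structure(out, class = c("sasa_profile", class(out)),
            pdb_id = attr(ensemble, "pdb_id"))
}

#' Classify residues as buried or exposed
#'
#' A residue is buried iff its relative SASA is strictly below the
#' threshold (default: 30 percent of the standard reference area).
#'
#' @param profile A [residue_sasa_profile()] result.
#' @param threshold Relative-SASA burial threshold (strict inequality).
#' @return The profile with an added `burial` column (`"buried"` /
#'   `"exposed"`).
#' @export
classify_burial <- function(profile, threshold = 0.30) {
  dplyr::mutate(profile,
                burial = ifelse(.data$sasa_ratio < threshold,
                                "buried", "exposed"))
}

#' @method glance sasa_profile
#' @export
glance.sasa_profile <- function(x, ...) {
  tibble::tibble(pdb_id = attr(x, "pdb_id") %||% NA_character_,
                 n_residues = nrow(x),
                 n_models = max(x$n_models),
                 n_buried = sum(x$sasa_ratio < 0.30),
                 mean_ratio = mean(x$sasa_ratio))
}

#' @method autoplot sasa_profile
#' @export
autoplot.sasa_profile <- function(object, threshold = 0.30, ...) {
  dat <- dplyr::mutate(
    tibble::as_tibble(object),
    label = paste0(.data$chain, .data$resno, tolower_aa(.data$resid)))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$label, .data$resno),
    y = .data$sasa_ratio, fill = .data$sasa_ratio < threshold)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c("FALSE" = "steelblue",
                                          "TRUE" = "firebrick")) +
    ggplot2::labs(x = NULL, y = "relative SASA") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chain), scales = "free_x",
                        space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

# "ASP" -> "Asp", the residue-name style used in reports.
tolower_aa <- function(x) {
  paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x))))
}

#' Write a SASA profile as TSV in the standard report layout
#'
#' Columns: Residue (e.g. `B44Asp`), SASA-Mean, SASA-Std, SASA-Intrinsic,
#' SASA-Ratio, values rounded to two decimals.
#'
#' @param profile A [residue_sasa_profile()] result.
#' @param path Output TSV path.
#' @return The written path, invisibly.
#' @export
write_sasa_tsv <- function(profile, path) {
  out <- tibble::tibble(
    Residue = paste0(profile$chain, profile$resno, tolower_aa(profile$resid)),
    `SASA-Mean` = sprintf("%.2f", profile$sasa_mean),
    `SASA-Std` = sprintf("%.2f", profile$sasa_std),
    `SASA-Intrinsic` = sprintf("%.2f", profile$sasa_intrinsic),
    `SASA-Ratio` = sprintf("%.2f", profile$sasa_ratio))
  readr::write_tsv(out, path)
  invisible(path)
}
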