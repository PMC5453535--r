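# Multi-model PDB input/output. Parsing and writing go through bio3d; the
# package-level container is a tidy atom table (one row per atom per model)
# carrying the ensemble identity as attributes.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

new_ensemble <- function(atoms, pdb_id) {
  atoms <- tibble::as_tibble(atoms)
  structure(atoms, pdb_id = pdb_id,
            class = c("ensemble", class(atoms)))
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", attr(x, "pdb_id"), ": ", n_models(x), " model(s), ",
      nrow(dplyr::distinct(tibble::as_tibble(x)[c("chain", "resno", "icode")])),
      " residues, ", nrow(x) / max(1L, n_models(x)),
      " atoms/model\n", sep = "")
  NextMethod()
}

#' Number of models in an ensemble
#'
#' @param ensemble An ensemble atom table from [read_multimodel_pdb()].
#' @return Integer model count.
#' @export
n_models <- function(ensemble) {
  if (nrow(ensemble) == 0L) return(0L)
  length(unique(ensemble$model))
}

#' Identifier of the structure an ensemble was read from
#'
#' @inheritParams n_models
#' @return Character scalar (4-character PDB id or filename stem).
#' @export
pdb_id <- function(ensemble) attr(ensemble, "pdb_id") %||% NA_character_

guess_element <- function(atom_name) {
  # Strip leading digits ("1HZ" -> "HZ"), then take the leading letter;
  # two-letter elements in protein work are rare and handled by the radii
  # fallback.
  core <- sub("^[0-9']+", "", atom_name)
  toupper(substr(core, 1L, 1L))
}

#' Read a (multi-model) PDB file into an ensemble atom table
#'
#' Each `MODEL`/`ENDMDL` block becomes one model; a file without `MODEL`
#' records yields a single-model ensemble. Hydrogens are retained. `HETATM`
#' records (waters, ligands) are excluded by default, as are non-standard
#' residue types, which are flagged with a warning.
#'
#' @param path Path to a PDB file.
#' @param keep_hetatm Keep `HETATM` records (default `FALSE`).
#' @param keep_nonstandard Keep residues whose type is not one of the 20
#'   standard amino acids (default `FALSE`; they are dropped with a warning).
#' @param collapse_altloc Resolve alternate locations to the
#'   highest-occupancy conformer (ties broken by file order); default `TRUE`.
#' @return A tibble of class `ensemble` with columns `model`, `chain`,
#'   `resno`, `icode`, `resid`, `atom`, `element`, `altloc`, `occ`, `x`,
#'   `y`, `z`, and attribute `pdb_id`.
#' @examples
#' pdb <- make_salt_bridge_fixture(fixture_spec("salt_bridge", distance = 3.8))
#' f <- tempfile(fileext = ".pdb")
#' writeLines(pdb, f)
#' read_multimodel_pdb(f)
#' @export
read_multimodel_pdb <- function(path, keep_hetatm = FALSE,
                                keep_nonstandard = FALSE,
                                collapse_altloc = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  raw <- readLines(path, warn = FALSE)
  nmod <- length(grep("^MODEL", raw))
  check_topology(raw)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = nmod > 1L, verbose = FALSE)),
    error = function(e) stop("not parseable as PDB: ", path, " (",
                             conditionMessage(e), ")")
  )
  if (!any(pdb$atom$type == "ATOM")) {
    stop("no ATOM records in ", path)
  }

  per_model <- tibble::tibble(
    chain = dplyr::coalesce(pdb$atom$chain, " "),
    resno = as.integer(pdb$atom$resno),
    icode = dplyr::coalesce(pdb$atom$insert, ""),
    resid = pdb$atom$resid,
    atom = pdb$atom$elety,
    element = dplyr::coalesce(pdb$atom$elesy, guess_element(pdb$atom$elety)),
    altloc = dplyr::coalesce(pdb$atom$alt, ""),
    occ = dplyr::coalesce(pdb$atom$o, 1),
    type = pdb$atom$type
  )

  nmodels <- max(1L, nmod)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (nrow(xyz) != nmodels) {
    # bio3d collapses to the frames it could read; trust its count
    nmodels <- nrow(xyz)
  }

  atoms <- purrr::map_dfr(seq_len(nmodels), function(k) {
    crd <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    dplyr::mutate(per_model, model = k,
                  x = crd[, 1L], y = crd[, 2L], z = crd[, 3L])
  })

  if (!keep_hetatm) atoms <- dplyr::filter(atoms, .data$type == "ATOM")
  atoms$type <- NULL

  nonstd <- setdiff(unique(atoms$resid), STANDARD_AA)
  if (length(nonstd) > 0L && !keep_nonstandard) {
    warning("dropping non-standard residue type(s): ",
            paste(nonstd, collapse = ", "))
    atoms <- dplyr::filter(atoms, .data$resid %in% STANDARD_AA)
  }
  if (nrow(atoms) == 0L) stop("no protein atoms left after filtering: ", path)

  if (collapse_altloc && any(atoms$altloc != "")) {
    atoms <- atoms |>
      dplyr::mutate(.ord = dplyr::row_number()) |>
      dplyr::group_by(.data$model, .data$chain, .data$resno, .data$icode,
                      .data$atom) |>
      dplyr::arrange(dplyr::desc(.data$occ), .data$.ord, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.ord) |>
      dplyr::select(-".ord")
  }

  atoms <- dplyr::relocate(atoms, "model")
  stem <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  new_ensemble(atoms, pdb_id = stem)
}

# Warn when MODEL blocks do not share the same residue/atom topology. Runs
# on the raw record text: identity is the (name, altloc, residue, chain,
# number, icode) field block of every ATOM record, in order.
check_topology <- function(raw) {
  starts <- grep("^MODEL", raw)
  if (length(starts) < 2L) return(invisible(NULL))
  ends <- grep("^ENDMDL", raw)
  if (length(ends) != length(starts)) return(invisible(NULL))
  keys <- purrr::map_chr(seq_along(starts), function(k) {
    block <- raw[starts[k]:ends[k]]
    atom <- grep("^ATOM", block, value = TRUE)
    paste(substr(atom, 13, 27), collapse = "|")
  })
  if (length(unique(keys)) > 1L) {
    warning("models do not share an identical atom topology")
  }
  invisible(NULL)
}

#' Extract one model of an ensemble
#'
#' @inheritParams n_models
#' @param index 1-based model number.
#' @return A tibble of the model's atoms (without the `model` column's
#'   siblings removed; the column is retained for provenance).
#' @export
get_model <- function(ensemble, index) {
  out <- dplyr::filter(tibble::as_tibble(ensemble), .data$model == index)
  if (nrow(out) == 0L) stop("no model with index ", index)
  out
}

#' Split an ensemble into single-model PDB files
#'
#' Writes one PDB file per model, named `<pdb_id>_model<k>.pdb`, with atom
#' order preserved.
#'
#' @inheritParams n_models
#' @param out_dir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly visible (one
#'   per model).
#' @export
split_ensemble <- function(ensemble, out_dir) {
  stopifnot(nrow(ensemble) > 0L)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory not writable: ", out_dir)
  }
  id <- pdb_id(ensemble)
  models <- sort(unique(ensemble$model))
  purrr::map_chr(models, function(k) {
    m <- get_model(ensemble, k)
    path <- file.path(out_dir, sprintf("%s_model%d.pdb", id, k))
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(m[, c("x", "y", "z")]))),
      resno = m$resno, resid = m$resid, chain = m$chain,
      insert = ifelse(m$icode == "", NA, m$icode),
      elety = m$atom, eleno = seq_len(nrow(m)),
      o = m$occ, b = rep(0, nrow(m)), elesy = m$element
    )
    path
  })
}

#' Select atoms from a model by chain, residue number and atom names
#'
#' Returns every atom matching the selection; an empty result is not an
#' error. When alternate locations survive in the table, only the
#' highest-occupancy altloc per atom name is returned (ties broken by row
#' order).
#'
#' @param model A single-model atom tibble (e.g. from [get_model()]).
#' @param chain Chain identifier.
#' @param residue_number PDB residue sequence number.
#' @param atom_names Character vector of atom names; `NULL` selects all
#'   atoms of the residue.
#' @param icode Insertion code (default `""`).
#' @return A tibble of matching atoms.
#' @export
select_atoms <- function(model, chain, residue_number, atom_names = NULL,
                         icode = "") {
  out <- dplyr::filter(tibble::as_tibble(model),
                       .data$chain == !!chain,
                       .data$resno == !!residue_number,
                       .data$icode == !!icode)
  if (!is.null(atom_names)) {
    out <- dplyr::filter(out, .data$atom %in% !!atom_names)
  }
  if (nrow(out) > 1L && any(out$altloc != "")) {
    out <- out |>
      dplyr::mutate(.ord = dplyr::row_number()) |>
      dplyr::group_by(.data$atom) |>
      dplyr::arrange(dplyr::desc(.data$occ), .data$.ord, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.ord) |>
      dplyr::select(-".ord")
  }
  out
}

#' @importFrom rlang .data %||%
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy ensemble
#' @export
tidy.ensemble <- function(x, ...) tibble::as_tibble(x)

#' @method glance ensemble
#' @export
glance.ensemble <- function(x, ...) {
  tibble::tibble(
    pdb_id = pdb_id(x),
    n_models = n_models(x),
    n_chains = length(unique(x$chain)),
    n_residues = nrow(dplyr::distinct(
      tibble::as_tibble(x)[c("chain", "resno", "icode")])),
    n_atoms = nrow(x)
  )
}
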