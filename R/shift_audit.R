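# Chemical-shift assignment completeness audit.
#
# Assignments are read either from an NMR-STAR (v3) assigned-chemical-shift
# loop or from a simplified TSV dialect (columns entity, residue, res_type,
# atom, shift). No R package in the stack reads NMR-STAR, so a minimal
# reader for the one loop this audit needs is implemented here.

#' Read a chemical-shift assignment table
#'
#' @param path An NMR-STAR v3 file containing an `_Atom_chem_shift` loop, or
#'   a TSV file with columns `entity`, `residue`, `res_type`, `atom`,
#'   `shift` (optional `ambiguity`).
#' @param format `"auto"` (sniff the content), `"nmrstar"` or `"tsv"`.
#' @return A tibble of class `assignment_table` with columns `entity`,
#'   `resno`, `resid`, `atom`, `shift`, `ambiguity`. Malformed rows are
#'   skipped with a warning; duplicate (entity, residue, atom) keys keep the
#'   first occurrence with a warning.
#' @export
read_assignments <- function(path, format = c("auto", "nmrstar", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read assignment file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("_Atom_chem_shift\\.", lines))) "nmrstar"
    else "tsv"
  }
  tab <- if (format == "nmrstar") parse_star_shifts(lines)
  else parse_tsv_shifts(path)

  dup <- duplicated(tab[c("entity", "resno", "atom")])
  if (any(dup)) {
    warning(sum(dup), " duplicate assignment key(s) dropped")
    tab <- tab[!dup, , drop = FALSE]
  }
  structure(tab, class = c("assignment_table", class(tab)))
}

parse_star_shifts <- function(lines) {
  lines <- trimws(lines)
  loop_starts <- which(lines == "loop_")
  if (length(loop_starts) == 0L) stop("no loop_ block in NMR-STAR input")
  for (start in loop_starts) {
    i <- start + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i])
      i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    rows <- list()
    while (i <= length(lines) && lines[i] != "stop_") {
      if (nzchar(lines[i]) && !startsWith(lines[i], "#")) {
        rows[[length(rows) + 1L]] <- strsplit(lines[i], "[[:space:]]+")[[1]]
      }
      i <- i + 1L
    }
    if (length(rows) == 0L) stop("assigned-chemical-shift loop is empty")
    field <- function(name, alt = NULL) {
      j <- match(paste0("_Atom_chem_shift.", name), tags)
      if (is.na(j) && !is.null(alt)) {
        j <- match(paste0("_Atom_chem_shift.", alt), tags)
      }
      j
    }
    j_ent <- field("Entity_ID", "Entity_assembly_ID")
    j_seq <- field("Seq_ID", "Comp_index_ID")
    j_res <- field("Comp_ID")
    j_atom <- field("Atom_ID")
    j_val <- field("Val")
    j_amb <- field("Ambiguity_code")
    if (any(is.na(c(j_seq, j_res, j_atom, j_val)))) {
      stop("assigned-chemical-shift loop lacks required tags")
    }
    ok <- purrr::map_lgl(rows, function(r) {
      length(r) >= length(tags) &&
        !is.na(suppressWarnings(as.numeric(r[j_val])))
    })
    if (any(!ok)) warning(sum(!ok), " malformed assignment row(s) skipped")
    rows <- rows[ok]
    if (length(rows) == 0L) stop("no usable assignment rows")
    get <- function(j, default = NA_character_) {
      if (is.na(j)) rep(default, length(rows))
      else purrr::map_chr(rows, j)
    }
    return(tibble::tibble(
      entity = get(j_ent, "1"),
      resno = as.integer(get(j_seq)),
      resid = toupper(get(j_res)),
      atom = toupper(get(j_atom)),
      shift = as.numeric(get(j_val)),
      ambiguity = suppressWarnings(as.integer(get(j_amb)))))
  }
  stop("no assigned-chemical-shift (_Atom_chem_shift) loop found")
}

parse_tsv_shifts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("entity", "residue", "res_type", "atom", "shift")
  if (!all(required %in% names(tab))) {
    stop("TSV assignment table must have columns: ",
         paste(required, collapse = ", "))
  }
  bad <- is.na(suppressWarnings(as.numeric(tab$shift))) |
    is.na(suppressWarnings(as.integer(tab$residue)))
  if (any(bad)) {
    warning(sum(bad), " malformed assignment row(s) skipped")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no usable assignment rows")
  tibble::tibble(
    entity = as.character(tab$entity),
    resno = as.integer(tab$residue),
    resid = toupper(tab$res_type),
    atom = toupper(tab$atom),
    shift = as.numeric(tab$shift),
    ambiguity = if ("ambiguity" %in% names(tab)) {
      as.integer(tab$ambiguity)
    } else NA_integer_)
}

parse_residue_selector <- function(sel) {
  if (is.character(sel)) {
    parts <- strsplit(sel, ":", fixed = TRUE)
    purrr::map_dfr(parts, function(p) {
      if (length(p) < 2L) stop("residue selector must be entity:resno[:type]")
      tibble::tibble(entity = p[1L], resno = as.integer(p[2L]),
                     resid = if (length(p) >= 3L) toupper(p[3L])
                     else NA_character_)
    })
  } else {
    tibble::as_tibble(sel)
  }
}

#' Report expected side-chain nuclei missing from an assignment table
#'
#' For each selected residue, lists every expected side-chain nucleus that
#' has no assigned chemical shift. Fully assigned residues contribute
#' nothing. Adding assignments can only shrink the report.
#'
#' @param table An [read_assignments()] result.
#' @param residues Residue selectors: `"entity:resno:RESTYPE"` strings or a
#'   tibble with columns `entity`, `resno`, `resid`.
#' @param expected Expected-nuclei table, see
#'   [expected_sidechain_nuclei()].
#' @param offset Integer offset added to selector residue numbers to map
#'   them onto the assignment table's numbering (per-entity deposition
#'   offsets are the user's to declare); default 0.
#' @return A tibble with one row per missing nucleus: `entity`, `resno`,
#'   `resid`, `nucleus`.
#' @export
find_missing_assignments <- function(table, residues,
                                     expected = expected_sidechain_nuclei(),
                                     offset = 0L) {
  sel <- parse_residue_selector(residues)
  out <- purrr::pmap_dfr(sel, function(entity, resno, resid) {
    resno_tab <- resno + offset
    hits <- dplyr::filter(tibble::as_tibble(table),
                          .data$entity == !!as.character(entity),
                          .data$resno == !!resno_tab)
    res_type <- resid
    if (nrow(hits) > 0L) {
      tab_type <- hits$resid[1L]
      if (!is.na(res_type) && res_type != tab_type) {
        warning("selector type ", res_type, " does not match table type ",
                tab_type, " at ", entity, ":", resno_tab)
      }
      if (is.na(res_type)) res_type <- tab_type
    }
    if (is.na(res_type)) {
      warning("residue type unknown for ", entity, ":", resno_tab,
              " (no assignments, no type in selector); skipped")
      return(NULL)
    }
    want <- dplyr::filter(expected, .data$resid == res_type)$atom
    miss <- setdiff(want, hits$atom)
    if (length(miss) == 0L) return(NULL)
    tibble::tibble(entity = as.character(entity), resno = resno,
                   resid = res_type, nucleus = miss)
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(entity = character(), resno = integer(),
                          resid = character(), nucleus = character())
  }
  out
}
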