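# Residue importance rule and SMA mutation impact annotation.
#
# A residue is potentially important if its side chain joins a salt bridge
# or a hydrogen bond in at least one ensemble model, or if its ensemble-mean
# SASA is below 30 percent of the standard reference value.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

# One-letter residue chemistry classes driving the impact typology.
residue_chemistry <- function() {
  tibble::tibble(
    code = c("D", "E", "K", "R", "H", "N", "Q", "S", "T", "Y", "C",
             "A", "V", "L", "I", "M", "F", "W", "P", "G", "X"),
    class = c("negative", "negative", "positive", "positive", "positive",
              "amide", "amide", "hydroxyl", "hydroxyl", "hydroxyl", "thiol",
              "hydrophobic", "hydrophobic", "hydrophobic", "hydrophobic",
              "hydrophobic", "hydrophobic", "hydrophobic", "hydrophobic",
              "glycine", "stop"))
}

sidechain_partners <- function(summaries) {
  # Long table of (residue, participating atom, kind) for every summary row,
  # keeping only side-chain participation: backbone carbonyl acceptors do
  # not flag the acceptor residue's side chain; a missing atom name
  # (group-center mode) is side-chain by construction.
  if (nrow(summaries) == 0L) {
    return(tibble::tibble(chain = character(), resno = integer(),
                          icode = character(), kind = character()))
  }
  backbone <- backbone_atom_names()
  side <- function(atom) is.na(atom) | !(atom %in% backbone)
  col <- function(s, name) {
    if (name %in% names(s)) s[[name]] else NA_character_
  }
  rows <- list()
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    if (s$kind == "salt_bridge") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chain = c(s$chain_a, s$chain_b), resno = c(s$resno_a, s$resno_b),
        icode = c(col(s, "icode_a"), col(s, "icode_b")), kind = s$kind,
        is_side = c(side(col(s, "atom_a")), side(col(s, "atom_b"))))
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chain = c(s$chain_d, s$chain_a), resno = c(s$resno_d, s$resno_a),
        icode = c(col(s, "icode_d"), col(s, "icode_a")), kind = s$kind,
        is_side = c(side(col(s, "donor_atom")),
                    side(col(s, "acceptor_atom"))))
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::filter(.data$is_side) |>
    dplyr::select(-"is_side") |>
    dplyr::distinct()
}

#' Classify potentially important residues
#'
#' Applies the three-part disjunctive rule to every residue of a SASA
#' profile: flagged if its side chain joins a detected salt bridge, if it
#' joins a detected hydrogen bond, or if it is buried (ensemble-mean
#' relative SASA strictly below `threshold`).
#'
#' @param profiles A [residue_sasa_profile()] result.
#' @param summaries Interaction summaries from [summarize_interactions()]:
#'   either one summary table, or several row-bound together; each must
#'   carry a `kind` column (added automatically when the attribute is
#'   present, see [bind_summaries()]).
#' @param threshold Burial threshold on the SASA ratio (strict).
#' @return A tibble of class `importance_record` with per-residue flags
#'   `in_salt_bridge`, `in_hydrogen_bond`, `buried` and their disjunction
#'   `important`.
#' @export
classify_important_residues <- function(profiles, summaries,
                                        threshold = 0.30) {
  summaries <- bind_summaries(summaries)
  partners <- sidechain_partners(summaries)
  sb <- dplyr::filter(partners, .data$kind == "salt_bridge")
  hb <- dplyr::filter(partners, .data$kind == "hydrogen_bond")
  key <- function(ch, no, ic) paste0(ch, ":", no, ":", ic)
  out <- tibble::as_tibble(profiles) |>
    dplyr::mutate(
      in_salt_bridge = key(.data$chain, .data$resno, .data$icode) %in%
        key(sb$chain, sb$resno, sb$icode),
      in_hydrogen_bond = key(.data$chain, .data$resno, .data$icode) %in%
        key(hb$chain, hb$resno, hb$icode),
      buried = .data$sasa_ratio < threshold,
      important = .data$in_salt_bridge | .data$in_hydrogen_bond |
        .data$buried) |>
    dplyr::select(dplyr::all_of(c("chain", "resno", "icode", "resid",
                                  "sasa_ratio", "in_salt_bridge",
                                  "in_hydrogen_bond", "buried", "important")))
  structure(out, class = c("importance_record", class(out)))
}

#' Combine interaction summaries of different kinds
#'
#' @param summaries A single `interaction_summary` or a list of them.
#' @return One tibble with a `kind` column.
#' @export
bind_summaries <- function(summaries) {
  if (inherits(summaries, "interaction_summary")) summaries <- list(summaries)
  if (is.data.frame(summaries)) {
    if (!"kind" %in% names(summaries)) {
      stop("summaries table must carry a `kind` column")
    }
    return(tibble::as_tibble(summaries))
  }
  purrr::map_dfr(summaries, function(s) {
    k <- attr(s, "kind")
    s <- tibble::as_tibble(s)
    if (!"kind" %in% names(s)) s$kind <- k %||% NA_character_
    s
  })
}

#' Cross-reference importance records with a mutation catalogue
#'
#' Matches catalogue positions against the residue numbers of the records,
#' restricted to the chain(s) that carry the SMN numbering (mutation
#' positions are sequence positions of one protein; partner chains must not
#' be matched).
#'
#' @param records A [classify_important_residues()] result.
#' @param catalogue A mutation catalogue, see [sma_mutations()].
#' @param chains Chain id(s) carrying the catalogue's numbering; `NULL`
#'   matches all chains.
#' @param important_only Keep only records flagged important (default
#'   `TRUE`).
#' @return Records joined with their matching mutations (one row per
#'   record-mutation match). Catalogue positions absent from the records
#'   are dropped with a warning.
#' @export
cross_reference_mutations <- function(records, catalogue, chains = NULL,
                                      important_only = TRUE) {
  rec <- tibble::as_tibble(records)
  if (!is.null(chains)) rec <- dplyr::filter(rec, .data$chain %in% chains)
  unmatched <- setdiff(catalogue$position, rec$resno)
  if (length(unmatched) > 0L) {
    warning("catalogue position(s) outside the analysed sequence: ",
            paste(sort(unmatched), collapse = ", "))
  }
  out <- dplyr::inner_join(rec, catalogue,
                           by = c(resno = "position"),
                           relationship = "many-to-many")
  if (important_only) out <- dplyr::filter(out, .data$important)
  out
}

parse_mutation <- function(mutation) {
  if (is.character(mutation) && length(mutation) == 1L) {
    m <- stringr::str_match(mutation, "^([A-Za-z])(\\d+)([A-Za-z])$")
    if (is.na(m[1, 1])) stop("cannot parse mutation label: ", mutation)
    tibble::tibble(position = as.integer(m[1, 3]), wt = toupper(m[1, 2]),
                   mut = toupper(m[1, 4]), label = toupper(mutation))
  } else {
    stopifnot(is.data.frame(mutation), nrow(mutation) == 1L)
    tibble::as_tibble(mutation)
  }
}

#' Annotate the structural impact of a missense or nonsense mutation
#'
#' Qualitative, table-driven sign logic: the category follows from the
#' wild-type and mutant side-chain chemistry, and the predicted change of
#' electrostatic sign follows from the category and the roles the wild-type
#' side chain plays in the supplied interactions. No energies are
#' estimated.
#'
#' Categories: a charged-to-hydrophobic substitution is `charge_removal`
#' (existing attractions are lost); negative-to-positive is
#' `charge_reversal_neg_to_pos` and amide-donor-to-negative is
#' `charge_reversal_donor_to_neg` (existing attractions become repulsions);
#' loss of a hydrophobic side chain (e.g. Ala to Gly) is
#' `hydrophobic_removal`; a premature stop is `truncation`; everything else
#' is `other`.
#'
#' @param mutation A one-row mutation tibble (columns `position`, `wt`,
#'   `mut`, `label`) or a label string such as `"D44V"`.
#' @param interactions Interactions involving the wild-type residue:
#'   detection rows or summaries (may be empty or `NULL`).
#' @return A one-row tibble of class `impact_annotation`: the mutation,
#'   `category`, `predicted_sign_change` (`"attraction_lost"`,
#'   `"attraction_to_repulsion"` or `"none"`) and `affected_interactions`
#'   (list column).
#' @export
annotate_mutation_impact <- function(mutation, interactions = NULL) {
  mut <- parse_mutation(mutation)
  chem <- residue_chemistry()
  cls <- function(code) {
    i <- match(code, chem$code)
    if (is.na(i)) stop("unknown residue code: ", code)
    chem$class[i]
  }
  wt_class <- cls(mut$wt)
  mut_class <- cls(mut$mut)

  category <- dplyr::case_when(
    mut_class == "stop" ~ "truncation",
    wt_class == "negative" & mut_class == "positive" ~
      "charge_reversal_neg_to_pos",
    wt_class == "amide" & mut_class == "negative" ~
      "charge_reversal_donor_to_neg",
    wt_class == "negative" & mut_class == "hydrophobic" ~ "charge_removal",
    wt_class == "positive" & mut_class == "hydrophobic" ~ "charge_removal",
    wt_class == "hydrophobic" & mut_class == "glycine" ~
      "hydrophobic_removal",
    TRUE ~ "other")

  n_inter <- if (is.null(interactions)) 0L else nrow(interactions)
  sign_change <- dplyr::case_when(
    n_inter == 0L ~ "none",
    category == "charge_removal" ~ "attraction_lost",
    category %in% c("charge_reversal_neg_to_pos",
                    "charge_reversal_donor_to_neg") ~
      "attraction_to_repulsion",
    TRUE ~ "none")

  out <- tibble::tibble(
    label = mut$label, position = mut$position, wt = mut$wt, mut = mut$mut,
    category = category, predicted_sign_change = sign_change,
    affected_interactions = list(
      if (is.null(interactions)) tibble::tibble() else
        tibble::as_tibble(interactions)))
  structure(out, class = c("impact_annotation", class(out)))
}
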