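# Packaged reference tables: standard SASA values, van der Waals radii,
# charged-group and donor/acceptor chemistry, side-chain nucleus nomenclature,
# and the SMA-linked SMN mutation catalogue.

#' Standard (intrinsic) per-residue SASA reference values
#'
#' Total solvent accessible surface area of each amino acid X in an extended
#' Ala-X-Ala reference state, in square Angstroms, as used by NACCESS. The
#' ratio of an observed residue SASA to this value is the relative SASA used
#' for burial classification.
#'
#' @return A tibble with columns `resid` (three-letter code) and
#'   `sasa_intrinsic` (squared Angstroms).
#' @examples
#' intrinsic_sasa()
#' @export
intrinsic_sasa <- function() {
  tibble::tibble(
    resid = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
              "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
              "TYR", "VAL"),
    sasa_intrinsic = c(107.95, 238.76, 143.94, 140.39, 134.28, 178.50, 172.25,
                       80.10, 182.88, 175.12, 178.63, 200.81, 194.15, 199.48,
                       136.13, 116.50, 139.27, 249.36, 212.76, 151.44)
  )
}

#' Van der Waals radii used for SASA calculation
#'
#' Chothia-style element radii (the set underlying the NACCESS reference
#' areas). Unknown elements fall back to the `"*"` entry.
#'
#' @return Named numeric vector of radii in Angstroms.
#' @export
vdw_radii <- function() {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, SE = 1.90,
    H = 1.00, D = 1.00, "*" = 1.80)
}

# Charged side-chain groups of the titratable residues. Polarity is fixed by
# residue type; His is treated as positively charged at both ring nitrogens
# (no pKa prediction).
charged_group_table <- function() {
  tibble::tibble(
    resid = c("ASP", "GLU", "LYS", "ARG", "HIS"),
    polarity = c("negative", "negative", "positive", "positive", "positive"),
    member_atoms = list(c("OD1", "OD2"), c("OE1", "OE2"), "NZ",
                        c("NE", "NH1", "NH2"), c("ND1", "NE2"))
  )
}

# Side-chain hydrogen-bond donor heavy atoms per residue type. Bound
# hydrogens are resolved geometrically (same residue, D-H < 1.3 A), not by
# name, so nomenclature variants (HZ1 vs 1HZ) are tolerated.
donor_atom_table <- function() {
  tibble::tribble(
    ~resid, ~atom,
    "LYS", "NZ",
    "ARG", "NE", "ARG", "NH1", "ARG", "NH2",
    "HIS", "ND1", "HIS", "NE2",
    "TRP", "NE1",
    "ASN", "ND2",
    "GLN", "NE2",
    "SER", "OG",
    "THR", "OG1",
    "TYR", "OH",
    "CYS", "SG"
  )
}

# Side-chain hydrogen-bond acceptor atoms per residue type. His ring
# nitrogens accept only when unprotonated (checked geometrically).
acceptor_atom_table <- function() {
  tibble::tribble(
    ~resid, ~atom,
    "ASP", "OD1", "ASP", "OD2",
    "GLU", "OE1", "GLU", "OE2",
    "ASN", "OD1",
    "GLN", "OE1",
    "HIS", "ND1", "HIS", "NE2",
    "SER", "OG",
    "THR", "OG1",
    "TYR", "OH",
    "MET", "SD"
  )
}

# Backbone atom names (hydrogens included); everything else is side chain.
backbone_atom_names <- function() {
  c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA", "HA2", "HA3",
    "HN")
}

#' Expected side-chain nuclei per residue type
#'
#' The default nomenclature table used by the assignment-completeness audit:
#' for every standard residue type, the side-chain heavy atoms and hydrogens
#' in PDB version-3 naming. The set is deliberately a superset of what a
#' typical solution-NMR study assigns (carboxylate oxygens, for instance, are
#' rarely observed); restrict it via the `expected` argument of
#' [find_missing_assignments()] when a narrower audit is wanted.
#'
#' @return A tibble with columns `resid` and `atom`.
#' @export
expected_sidechain_nuclei <- function() {
  def <- list(
    ALA = c("CB", "HB1", "HB2", "HB3"),
    ARG = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3",
            "NE", "HE", "CZ", "NH1", "HH11", "HH12", "NH2", "HH21", "HH22"),
    ASN = c("CB", "HB2", "HB3", "CG", "OD1", "ND2", "HD21", "HD22"),
    ASP = c("CB", "HB2", "HB3", "CG", "OD1", "OD2"),
    CYS = c("CB", "HB2", "HB3", "SG", "HG"),
    GLN = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "OE1",
            "NE2", "HE21", "HE22"),
    GLU = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "OE1", "OE2"),
    GLY = character(),
    HIS = c("CB", "HB2", "HB3", "CG", "ND1", "HD1", "CD2", "HD2",
            "CE1", "HE1", "NE2", "HE2"),
    ILE = c("CB", "HB", "CG1", "HG12", "HG13", "CG2", "HG21", "HG22",
            "HG23", "CD1", "HD11", "HD12", "HD13"),
    LEU = c("CB", "HB2", "HB3", "CG", "HG", "CD1", "HD11", "HD12", "HD13",
            "CD2", "HD21", "HD22", "HD23"),
    LYS = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3",
            "CE", "HE2", "HE3", "NZ", "HZ1", "HZ2", "HZ3"),
    MET = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "SD", "CE",
            "HE1", "HE2", "HE3"),
    PHE = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "CD2", "HD2",
            "CE1", "HE1", "CE2", "HE2", "CZ", "HZ"),
    PRO = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3"),
    SER = c("CB", "HB2", "HB3", "OG", "HG"),
    THR = c("CB", "HB", "CG2", "HG21", "HG22", "HG23", "OG1", "HG1"),
    TRP = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "CD2", "NE1", "HE1",
            "CE2", "CE3", "HE3", "CZ2", "HZ2", "CZ3", "HZ3", "CH2", "HH2"),
    TYR = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "CD2", "HD2",
            "CE1", "HE1", "CE2", "HE2", "CZ", "OH", "HH"),
    VAL = c("CB", "HB", "CG1", "HG11", "HG12", "HG13",
            "CG2", "HG21", "HG22", "HG23")
  )
  tibble::tibble(resid = rep(names(def), lengths(def)),
                 atom = unlist(def, use.names = FALSE))
}

#' SMA-linked SMN mutation catalogue
#'
#' Point mutations of the human SMN protein reported in spinal muscular
#' atrophy patients that fall inside (or are discussed alongside) the
#' structurally determined SMN regions: the Gemin2-binding domain, the Tudor
#' domain, and the C-terminal region. `mut == "X"` marks a nonsense
#' (premature-stop) mutation. Users may extend the catalogue with
#' [read_mutation_catalogue()].
#'
#' @return A tibble with columns `position`, `wt`, `mut`, `label`, `source`.
#' @examples
#' sma_mutations()
#' @export
sma_mutations <- function() {
  tibble::tribble(
    ~position, ~wt, ~mut, ~label,
    2L,   "A", "G", "A2G",
    44L,  "D", "V", "D44V",
    92L,  "W", "S", "W92S",
    102L, "W", "X", "W102X",
    111L, "A", "G", "A111G",
    116L, "I", "F", "I116F",
    134L, "E", "K", "E134K",
    136L, "Q", "E", "Q136E",
    279L, "G", "C", "G279C",
    279L, "G", "V", "G279V"
  ) |>
    dplyr::mutate(source = "packaged")
}

#' Read a user mutation catalogue from TSV
#'
#' @param path TSV file with columns `position`, `wt`, `mut`, `label`.
#' @return A tibble in the same shape as [sma_mutations()] with
#'   `source = "user"`.
#' @export
read_mutation_catalogue <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           position = readr::col_integer(),
                           wt = readr::col_character(),
                           mut = readr::col_character(),
                           label = readr::col_character()
                         ))
  required <- c("position", "wt", "mut", "label")
  if (!all(required %in% names(tab))) {
    stop("mutation catalogue must have columns: ",
         paste(required, collapse = ", "))
  }
  bad <- tab$wt == tab$mut | tab$position < 1L
  if (any(bad)) {
    warning(sum(bad), " malformed catalogue row(s) dropped")
    tab <- tab[!bad, , drop = FALSE]
  }
  dplyr::mutate(tab[required], source = "user")
}

#' Reference interface hydrogen-bond geometries for the SMN-Gemin2 complex
#'
#' Curated single-model geometries and ensemble distributions of the four
#' hydrogen bonds reported at the SMN-Gemin2 interface of the solution
#' structure 2leh (32 models): Lys45(B) to Gln109(A)/Gln105(A) and
#' Trp124(A) to Asp36(B). Single-model rows carry the geometry of the one
#' model in which each bond was detected; distribution rows carry the
#' mean and standard deviation over all 32 models. Useful as a no-download
#' check that the detection criteria reproduce a published census.
#'
#' @return A tibble with columns `hb`, `row_type` (`"single_model"` or
#'   `"distribution"`), `acceptor`, `donor`, `hydrogen`, `d_da`, `d_ha`,
#'   `angle_adh`, and for distribution rows `d_da_sd`, `d_ha_sd`,
#'   `angle_adh_sd`.
#' @export
smn_interface_hbond_geometries <- function() {
  tibble::tribble(
    ~hb,   ~row_type,      ~acceptor,        ~donor,        ~hydrogen,
    ~d_da, ~d_da_sd, ~d_ha, ~d_ha_sd, ~angle_adh, ~angle_adh_sd,
    "HB1", "single_model", "OE1 A109Gln", "NZ B45Lys", "HZ1 B45Lys",
    2.63, NA, 1.68, NA, 18.83, NA,
    "HB1", "distribution", "OE1 A109Gln", "NZ B45Lys", "HZ1 B45Lys",
    4.11, 1.30, 4.13, 1.41, 86.43, 41.56,
    "HB2", "single_model", "O A105Gln", "NZ B45Lys", "HZ3 B45Lys",
    2.70, NA, 1.68, NA, 9.22, NA,
    "HB2", "distribution", "O A105Gln", "NZ B45Lys", "HZ3 B45Lys",
    3.73, 0.97, 3.76, 1.28, 84.34, 41.27,
    "HB3", "single_model", "O A105Gln", "NZ B45Lys", "HZ2 B45Lys",
    2.94, NA, 2.06, NA, 26.72, NA,
    "HB3", "distribution", "O A105Gln", "NZ B45Lys", "HZ2 B45Lys",
    3.73, 0.97, 3.64, 1.18, 76.15, 33.94,
    "HB4", "single_model", "OD2 B36Asp", "NE1 A124Trp", "HE1 A124Trp",
    2.76, NA, 1.95, NA, 28.37, NA,
    "HB4", "distribution", "OD2 B36Asp", "NE1 A124Trp", "HE1 A124Trp",
    5.91, 1.15, 5.53, 1.19, 62.29, 10.49
  )
}

#' Reference interface salt-bridge geometries for the SMN-Gemin2 complex
#'
#' Curated atom-pair salt bridges between SMN Asp36(B) and Gemin2
#' His120(A)/His123(A) in model 15 of the solution structure 2leh, with the
#' corresponding 32-model distance distributions.
#'
#' @return A tibble with columns `sb`, `atom_a`, `atom_b`, `distance`
#'   (model-15 value), `distance_mean`, `distance_sd` (32-model
#'   distribution).
#' @export
smn_interface_saltbridge_geometries <- function() {
  tibble::tribble(
    ~sb,   ~atom_a,         ~atom_b,        ~distance, ~distance_mean, ~distance_sd,
    "SB1", "NE2 A123His", "OD2 B36Asp", 3.1, 5.73, 0.93,
    "SB2", "ND1 A123His", "OD1 B36Asp", 4.0, 7.04, 1.01,
    "SB3", "ND1 A120His", "OD1 B36Asp", 2.6, 6.87, 0.94,
    "SB4", "NE2 A120His", "OD1 B36Asp", 3.7, 5.57, 0.64
  )
}
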