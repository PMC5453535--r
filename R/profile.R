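# One-call composition of the full per-structure analysis: detection,
# ensemble summaries, SASA profiling, importance classification and
# mutation impact annotation, with optional TSV/JSON report output.

#' Run the full structural profile on one or more PDB files
#'
#' For each input structure: reads the ensemble, summarizes salt bridges
#' and hydrogen bonds across models, computes the per-residue SASA profile
#' and burial, classifies potentially important residues, cross-references
#' them with the mutation catalogue, and annotates each matched mutation
#' with its electrostatic impact category. A failing structure is reported
#' in the bundle without aborting the remaining inputs.
#'
#' @param paths Character vector of PDB file paths (at least one).
#' @param config A [detection_config()].
#' @param catalogue Mutation catalogue tibble (default [sma_mutations()]).
#' @param smn_chains Chain id(s) carrying the catalogue's residue
#'   numbering, or `NULL` for all chains.
#' @param burial_threshold Relative-SASA burial threshold.
#' @param n_sphere_points SASA quadrature points.
#' @param out_dir If non-`NULL`, TSV reports and a JSON manifest are
#'   written there.
#' @return A list of class `profile_bundle`: one entry per structure with
#'   elements `ensemble`, `salt_bridges`, `hydrogen_bonds`, `sasa`,
#'   `importance`, `matched_mutations`, `impacts` (or `error`), plus a
#'   `manifest` entry recording configuration and inputs.
#' @export
run_full_profile <- function(paths, config = detection_config(),
                             catalogue = sma_mutations(),
                             smn_chains = NULL,
                             burial_threshold = 0.30,
                             n_sphere_points = 960,
                             out_dir = NULL) {
  if (length(paths) == 0L) stop("no input structures given")
  results <- purrr::map(paths, function(path) {
    tryCatch({
      ens <- read_multimodel_pdb(path)
      sb <- summarize_interactions(ens, config, "salt_bridge")
      hb <- summarize_interactions(ens, config, "hydrogen_bond")
      prof <- residue_sasa_profile(ens, n_sphere_points = n_sphere_points,
                                   sd = config$sd) |>
        classify_burial(threshold = burial_threshold)
      imp <- classify_important_residues(
        prof, list(sb, hb), threshold = burial_threshold)
      matched <- withCallingHandlers(
        cross_reference_mutations(imp, catalogue, chains = smn_chains),
        warning = function(w) invokeRestart("muffleWarning"))
      combined <- bind_summaries(list(sb, hb))
      impacts <- purrr::map_dfr(seq_len(nrow(matched)), function(i) {
        m <- matched[i, ]
        inter <- combined[involves_residue(combined, m$chain, m$resno), ,
                          drop = FALSE]
        annotate_mutation_impact(
          tibble::tibble(position = m$resno, wt = m$wt, mut = m$mut,
                         label = m$label),
          inter)
      })
      list(ensemble = ens, salt_bridges = sb, hydrogen_bonds = hb,
           sasa = prof, importance = imp, matched_mutations = matched,
           impacts = impacts)
    }, error = function(e) list(error = conditionMessage(e)))
  })
  names(results) <- purrr::map_chr(paths, function(p) {
    sub("\\.(pdb|ent)$", "", basename(p), ignore.case = TRUE)
  })
  manifest <- list(
    tool = "smnprofiler",
    version = as.character(utils::packageVersion("smnprofiler")),
    config = unclass(config),
    burial_threshold = burial_threshold,
    n_sphere_points = n_sphere_points,
    inputs = purrr::map(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  bundle <- structure(c(results, list(manifest = manifest)),
                      class = "profile_bundle")
  if (!is.null(out_dir)) write_profile_bundle(bundle, out_dir)
  bundle
}

involves_residue <- function(tbl, chain, resno) {
  hit <- rep(FALSE, nrow(tbl))
  for (side in c("a", "b", "d")) {
    ch <- paste0("chain_", side)
    rn <- paste0("resno_", side)
    if (all(c(ch, rn) %in% names(tbl))) {
      hit <- hit | (!is.na(tbl[[ch]]) & tbl[[ch]] == chain &
                      tbl[[rn]] == resno)
    }
  }
  hit
}

#' Write a profile bundle as TSV reports plus a JSON manifest
#'
#' @param bundle A [run_full_profile()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_profile_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  for (id in setdiff(names(bundle), "manifest")) {
    entry <- bundle[[id]]
    if (!is.null(entry$error)) next
    for (what in c("salt_bridges", "hydrogen_bonds", "importance",
                   "matched_mutations")) {
      tab <- tibble::as_tibble(entry[[what]])
      tab <- dplyr::select(tab, -dplyr::any_of("model_indices"))
      p <- file.path(out_dir, paste0(id, "_", what, ".tsv"))
      readr::write_tsv(tab, p)
      written <- c(written, p)
    }
    p <- file.path(out_dir, paste0(id, "_sasa.tsv"))
    write_sasa_tsv(entry$sasa, p)
    written <- c(written, p)
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE, digits = NA)
  written <- c(written, mp)
  invisible(written)
}

#' @export
print.profile_bundle <- function(x, ...) {
  ids <- setdiff(names(x), "manifest")
  cat("<profile_bundle> ", length(ids), " structure(s)\n", sep = "")
  for (id in ids) {
    e <- x[[id]]
    if (!is.null(e$error)) {
      cat("  ", id, ": ERROR - ", e$error, "\n", sep = "")
    } else {
      cat("  ", id, ": ", n_models(e$ensemble), " models, ",
          nrow(e$salt_bridges), " salt-bridge pair(s), ",
          nrow(e$hydrogen_bonds), " hydrogen-bond pair(s), ",
          sum(e$importance$important), "/", nrow(e$importance),
          " residues important\n", sep = "")
    }
  }
  invisible(x)
}
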