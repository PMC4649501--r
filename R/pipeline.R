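#' Run the full apo/holo structural analysis
#'
#' Orchestrates the whole conformational-change workflow on an apo/holo
#' structure pair: read both files, annotate helices, compute EF-hand
#' opening angles and their apo-to-holo differences, extract metal
#' coordination spheres from the holo form, compute per-residue SASA for
#' both forms with exposure-change flagging, cluster exposed hydrophobic
#' patches on the holo form, and (optionally) measure peptide-interface
#' burial. Each stage runs independently; a stage failure is recorded in
#' the bundle's `errors` element without aborting the rest.
#'
#' @param apo_path,holo_path Coordinate files (PDB or mmCIF).
#' @param chain Protein chain to analyse (default `"A"`).
#' @param annotations Helix annotation tibble, a registry name (see
#'   [pef_registry()]), or `NULL` to auto-assign from the apo structure
#'   with boundaries trimmed to residues resolved in both forms (the same
#'   ranges are then used for both forms, so the deltas measure
#'   conformational change, not boundary re-assignment).
#' @param metal_element Metal to search for (default calcium).
#' @param metal_cutoff Metal-ligand cutoff, angstrom.
#' @param sasa_threshold Relative SASA-change threshold, percent.
#' @param sasa_points Shrake-Rupley points per atom.
#' @param hbond_cutoff Hydrogen-bond heavy-atom cutoff, angstrom.
#' @param patch_linkage Patch single-linkage cutoff, angstrom.
#' @param interface_chains Optional length-2 list of chain sets for
#'   peptide-interface burial on the holo form.
#' @param out_dir Optional directory: every report is also written there as
#'   TSV (fixed column order and float precision, so re-runs are
#'   byte-identical).
#'
#' @return A `pef_analysis` list: `config`, `annotations`, `angles`
#'   (apo+holo), `deltas`, `metal_sites`, `delta_sasa`, `patches`,
#'   `interface` (or `NULL`), `hbonds` (interface hydrogen bonds, when
#'   interface chains are given) and `errors`.
#' @export
run_full_analysis <- function(apo_path, holo_path, chain = "A",
                              annotations = NULL,
                              metal_element = "CA", metal_cutoff = 2.9,
                              sasa_threshold = 30, sasa_points = 960,
                              hbond_cutoff = 3.5, patch_linkage = 6.5,
                              interface_chains = NULL, out_dir = NULL) {
  for (p in c(apo_path, holo_path)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  stopifnot(metal_cutoff > 0, sasa_threshold > 0, hbond_cutoff > 0,
            patch_linkage > 0)
  config <- list(apo_path = apo_path, holo_path = holo_path, chain = chain,
                 metal_element = metal_element, metal_cutoff = metal_cutoff,
                 sasa_threshold = sasa_threshold, sasa_points = sasa_points,
                 hbond_cutoff = hbond_cutoff, patch_linkage = patch_linkage)
  apo <- read_structure(apo_path)
  holo <- read_structure(holo_path)
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  ann <- run_stage("annotations", {
    if (is.data.frame(annotations)) as_tibble(annotations)
    else if (is.character(annotations)) pef_registry(annotations)
    else derive_registry(apo, chain, other = holo)
  })
  angles <- deltas <- NULL
  if (!is.null(ann)) {
    angles <- run_stage("angles", bind_rows(
      efhand_angles(apo, chain, ann, label = "apo"),
      efhand_angles(holo, chain, ann, label = "holo")))
    if (!is.null(angles)) {
      deltas <- run_stage("deltas", delta_table(
        angles[angles$label == "apo", ], angles[angles$label == "holo", ]))
    }
  }
  metal_sites <- run_stage("metal_sites",
                           find_metal_sites(holo, metal_element, metal_cutoff,
                                            annotations = ann))
  dsasa <- run_stage("delta_sasa", {
    sa <- compute_sasa(keep_chain(apo, chain), n_points = sasa_points)
    sh <- compute_sasa(keep_chain(holo, chain), n_points = sasa_points)
    delta_sasa(sa, sh, threshold = sasa_threshold)
  })
  patches <- run_stage("patches", {
    sh <- compute_sasa(keep_chain(holo, chain), n_points = sasa_points)
    hydrophobic_patches(keep_chain(holo, chain), sh, linkage = patch_linkage)
  })
  interface <- hbonds <- NULL
  if (!is.null(interface_chains)) {
    interface <- run_stage("interface",
                           interface_burial(holo, interface_chains[[1]],
                                            interface_chains[[2]],
                                            n_points = sasa_points))
    hbonds <- run_stage("hbonds", {
      bind_rows(lapply(interface_chains[[1]], function(ca) {
        bind_rows(lapply(interface_chains[[2]], function(cb) {
          find_hbonds(holo, ca, b_chain = cb, cutoff = hbond_cutoff)
        }))
      }))
    })
  }
  bundle <- structure(list(config = config, annotations = ann,
                           angles = angles, deltas = deltas,
                           metal_sites = metal_sites, delta_sasa = dsasa,
                           patches = patches, interface = interface,
                           hbonds = hbonds, errors = errors),
                      class = "pef_analysis")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

keep_chain <- function(s, chain) {
  new_structure(as_tibble(s)[s$chain == chain, ],
                entry_id = attr(s, "entry_id"),
                source_format = attr(s, "source_format"))
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x) > 0) {
      flat <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
      write_report(flat, file.path(out_dir, paste0(name, ".tsv")), "tsv")
    }
  }
  emit(bundle$annotations, "annotations")
  emit(bundle$angles, "angles")
  emit(bundle$deltas, "deltas")
  emit(bundle$metal_sites, "metal_sites")
  emit(bundle$delta_sasa, "delta_sasa")
  emit(bundle$patches, "patches")
  emit(bundle$interface, "interface")
  emit(bundle$hbonds, "hbonds")
  jsonlite::write_json(
    c(bundle$config,
      list(errors = bundle$errors,
           flagged_residues = if (!is.null(bundle$delta_sasa))
             bundle$delta_sasa$res_id[bundle$delta_sasa$flagged] else integer())),
    file.path(out_dir, "bundle.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = 4)
  invisible(out_dir)
}

#' @export
print.pef_analysis <- function(x, ...) {
  cat("# pef_analysis bundle\n")
  cat(sprintf("  apo:  %s\n  holo: %s (chain %s)\n",
              x$config$apo_path, x$config$holo_path, x$config$chain))
  if (!is.null(x$deltas)) {
    cat("  angle deltas (holo - apo, degrees):\n")
    for (i in seq_len(nrow(x$deltas))) {
      cat(sprintf("    %-6s %+6.1f\n", x$deltas$angle[i], x$deltas$delta[i]))
    }
  }
  if (!is.null(x$metal_sites)) {
    cat(sprintf("  metal sites: %d\n", nrow(x$metal_sites)))
  }
  if (!is.null(x$delta_sasa)) {
    cat(sprintf("  SASA-flagged residues: %d\n", sum(x$delta_sasa$flagged)))
  }
  if (length(x$errors) > 0) {
    cat(sprintf("  stage errors: %s\n", paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}

#' Plot apo-to-holo opening-angle changes
#'
#' @param deltas A delta table from [delta_table()].
#' @return A ggplot bar chart of signed angle changes per EF-hand.
#' @export
plot_deltas <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(x = .data$angle, y = .data$delta,
                                       fill = .data$delta > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = expression(Delta * theta ~ "(degrees)")) +
    ggplot2::theme_minimal()
}

#' Plot an apo/holo exposure-change profile
#'
#' @param dsasa A report from [delta_sasa()].
#' @return A ggplot of relative SASA change along the sequence, flagged
#'   residues highlighted.
#' @export
plot_delta_sasa <- function(dsasa) {
  ggplot2::ggplot(dsasa, ggplot2::aes(x = .data$res_id,
                                      y = .data$relative_change)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$flagged), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residue (author numbering)",
                  y = "SASA change (%)") +
    ggplot2::theme_minimal()
}
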