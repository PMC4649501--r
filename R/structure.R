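#' Tidy atom-table representation of a macromolecular structure
#'
#' A `pef_structure` is a tibble with one row per atom and the columns
#' `chain`, `res_id` (author residue numbering, as deposited), `ins`
#' (insertion code, `""` when absent), `res_name` (3-letter code),
#' `atom_name`, `element`, `x`, `y`, `z` (angstrom), `occ`, `b` and `het`
#' (logical, `TRUE` for HETATM records: ions, waters, ligand peptide chains
#' that were deposited as heteroatoms). Author numbering is never rewritten,
#' so residue labels such as Glu97 or Trp105 in reports refer to the same
#' residues as in the source file.
#'
#' @param atoms A data frame with the columns listed above.
#' @param entry_id Entry identifier (e.g. a PDB code), stored as an attribute.
#' @param source_format `"pdb"`, `"cif"` or `"generated"`.
#' @param model Model number the coordinates came from.
#'
#' @return A `pef_structure` tibble.
#' @export
new_structure <- function(atoms, entry_id = "", source_format = "generated",
                          model = 1L) {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "res_id", "ins", "res_name", "atom_name", "element",
              "x", "y", "z", "occ", "b", "het")
  missing_cols <- setdiff(needed, names(atoms))
  if ("ins" %in% missing_cols) atoms$ins <- ""
  if ("occ" %in% missing_cols) atoms$occ <- 1
  if ("b" %in% missing_cols) atoms$b <- 0
  if ("het" %in% missing_cols) atoms$het <- FALSE
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  atoms <- atoms[, needed]
  atoms$res_id <- as.integer(atoms$res_id)
  if (nrow(atoms) == 0) abort("structure has no atoms (empty model)")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates in atom table")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE)) {
    abort("occupancies must lie in [0, 1]")
  }
  atoms <- arrange(atoms, .data$chain, .data$res_id, .data$ins)
  structure(atoms,
            class = c("pef_structure", class(tibble())),
            entry_id = entry_id,
            source_format = source_format,
            model = as.integer(model))
}

#' @export
print.pef_structure <- function(x, ...) {
  cat(sprintf("# pef_structure: %s (%s, model %d)\n",
              if (nzchar(attr(x, "entry_id"))) attr(x, "entry_id") else "<unnamed>",
              attr(x, "source_format"), attr(x, "model")))
  res <- dplyr::n_distinct(paste(x$chain, x$res_id, x$ins))
  cat(sprintf("# %d atoms, %d residues, chains: %s\n",
              nrow(x), res, paste(unique(x$chain), collapse = " ")))
  NextMethod()
}

# keep the class and attributes through dplyr verbs used internally
#' @export
`[.pef_structure` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) out <- restore_structure_attrs(out, x)
  out
}

restore_structure_attrs <- function(out, template) {
  attr(out, "entry_id") <- attr(template, "entry_id")
  attr(out, "source_format") <- attr(template, "source_format")
  attr(out, "model") <- attr(template, "model")
  class(out) <- unique(c("pef_structure", class(tibble())))
  out
}

#' Coordinates of an atom table as a numeric matrix
#'
#' @param atoms A `pef_structure` or any data frame with `x`, `y`, `z`.
#' @return An n x 3 matrix of coordinates in angstrom.
#' @export
atom_coords <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' Concatenate structures into one atom table
#'
#' Used by the synthetic generators to assemble multi-component fixtures
#' (e.g. three calcium sites in one model). Chains are kept as given.
#'
#' @param ... `pef_structure` objects.
#' @param entry_id Entry id for the combined structure.
#' @return A `pef_structure`.
#' @export
bind_structures <- function(..., entry_id = "combined") {
  parts <- list(...)
  new_structure(bind_rows(lapply(parts, as_tibble)),
                entry_id = entry_id, source_format = "generated")
}

guess_element <- function(atom_name, res_name) {
  # PDB columns 77-78 absent: infer from the atom name, honouring the
  # convention that a leading digit (1HB2 etc.) precedes the element letter
  nm <- gsub("[0-9']", "", toupper(trimws(atom_name)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "CU", "NI") |
           (two == "CA" & toupper(res_name) == "CA"),
         two, substr(nm, 1, 1))
}
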