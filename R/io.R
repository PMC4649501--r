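#' Read a PDB or mmCIF coordinate file into a tidy atom table
#'
#' Parses the file with bio3d and returns a [new_structure()] tibble using
#' author residue numbering throughout. Hetero records (metal ions, waters,
#' peptide chains deposited as HETATM) are retained and flagged in the `het`
#' column. Where a residue carries alternate conformers, the
#' highest-occupancy conformer is kept (ties broken by altloc identifier
#' order), so downstream geometry is single-conformer.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (from the extension), `"pdb"` or `"cif"`.
#' @param model Model number to load from multi-model files (default 1).
#'
#' @return A `pef_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = model > 1L,
                         rm.alt = FALSE),
    error = function(e) abort(paste0("failed to parse ", path, " as ",
                                     toupper(format), ": ", conditionMessage(e)))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) abort(paste0("empty model in ", path))
  if (model > 1L) {
    xyz <- pdb$xyz
    if (is.matrix(xyz) && nrow(xyz) >= model) {
      m <- matrix(xyz[model, ], ncol = 3, byrow = TRUE)
      at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
    } else {
      abort(sprintf("model %d requested but file holds %d model(s)",
                    model, if (is.matrix(xyz)) nrow(xyz) else 1L))
    }
  }
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "", NA, at$elesy)))
  fallback <- guess_element(at$elety, at$resid)
  elem[is.na(elem)] <- fallback[is.na(elem)]
  atoms <- tibble(
    chain = ifelse(is.na(at$chain), "", at$chain),
    res_id = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    res_name = at$resid,
    atom_name = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    het = at$type == "HETATM",
    alt = ifelse(is.na(at$alt), "", at$alt)
  )
  atoms <- collapse_altlocs(atoms)
  new_structure(atoms,
                entry_id = toupper(sub("\\.[^.]*$", "", basename(path))),
                source_format = format, model = model)
}

collapse_altlocs <- function(atoms) {
  atoms |>
    group_by(.data$chain, .data$res_id, .data$ins, .data$res_name,
             .data$atom_name) |>
    arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-"alt")
}

#' Write a structure to a PDB-format file
#'
#' Fixed-width PDB ATOM/HETATM records, coordinates at 3 decimals.
#' Round-trips through [read_structure()] without coordinate loss at the
#' format's precision.
#'
#' @param s A `pef_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  name4 <- vapply(seq_len(nrow(s)), function(i) {
    nm <- s$atom_name[i]
    if (nchar(nm) >= 4) return(substr(nm, 1, 4))
    if (nchar(s$element[i]) == 1) sprintf("%-4s", paste0(" ", nm))
    else sprintf("%-4s", nm)
  }, character(1))
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(s$het, "HETATM", "ATOM"),
    seq_len(nrow(s)) %% 100000L, name4, " ",
    s$res_name, substr(paste0(s$chain, " "), 1, 1), s$res_id,
    substr(paste0(s$ins, " "), 1, 1),
    s$x, s$y, s$z, s$occ, s$b, s$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms by chain, author residue range and atom name
#'
#' @param s A `pef_structure`.
#' @param chain Chain identifier.
#' @param start,end Inclusive author residue numbers (default: whole chain).
#' @param atoms Optional character vector of atom names (e.g. `"CA"`).
#'
#' @return A `pef_structure` tibble of the matching atoms, in file order;
#'   empty when the range matches nothing.
#' @export
select_atoms <- function(s, chain, start = -Inf, end = Inf, atoms = NULL) {
  chains <- unique(s$chain)
  if (!chain %in% chains) {
    abort(sprintf("chain '%s' not in structure (available: %s)",
                  chain, paste(chains, collapse = ", ")))
  }
  if (any(start > end)) abort("selection start must be <= end")
  out <- s[s$chain == chain & s$res_id >= start & s$res_id <= end, ]
  if (!is.null(atoms)) out <- out[out$atom_name %in% atoms, ]
  out
}

#' One-letter amino-acid sequence of a selection
#'
#' @param s A `pef_structure` (or selection thereof).
#' @return A character vector of one-letter codes, one per residue.
#' @export
residue_sequence <- function(s) {
  res <- distinct(as_tibble(s), .data$chain, .data$res_id, .data$ins,
                  .data$res_name)
  aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  unname(ifelse(res$res_name %in% names(aa3), aa3[res$res_name], "X"))
}

#' Write an analysis report as TSV or JSON
#'
#' Column order is preserved and floating-point values are written at 4
#' decimals, so repeated runs produce byte-identical files.
#'
#' @param x A data frame (any of the package's report tibbles).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- as_tibble(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], round, digits = 4)
  if (format == "tsv") {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report path.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
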