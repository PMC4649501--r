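#' Annotate alpha-helices on a protein chain
#'
#' Three annotation routes:
#' \describe{
#'   \item{`auto`}{A C-alpha-geometry secondary-structure assignment in the
#'     P-SEA spirit: residue i is helical when the Cα(i)–Cα(i+3) and
#'     Cα(i)–Cα(i+4) distances fall in the canonical alpha-helix windows
#'     (about 5.0 and 6.2 angstrom). Runs are merged and segments shorter
#'     than `min_length` dropped.}
#'   \item{`registry`}{Built-in approximate helix tables for the PEF family
#'     members (see [pef_registry()]).}
#'   \item{`file`}{A user TSV with columns `helix`, `chain`, `start`, `end`.}
#' }
#' With `label = "pef"` (the default) the 8 longest segments are named
#' A–H in sequence order, the PEF-domain convention; fewer than 8 segments
#' is then an error suggesting registry/file mode. With `label = "none"`
#' segments are returned as found.
#'
#' @param s A `pef_structure`.
#' @param chain Chain to annotate.
#' @param method `"auto"`, `"registry"` or `"file"`.
#' @param registry Registry name for `method = "registry"` (see
#'   [pef_registry()]).
#' @param file Annotation TSV path for `method = "file"`.
#' @param label `"pef"` (A–H labelling) or `"none"` (raw segments).
#' @param min_length Minimum helix length in residues for auto mode.
#'
#' @return A tibble: `helix`, `chain`, `start`, `end` (author numbering).
#' @export
assign_helices <- function(s, chain, method = c("auto", "registry", "file"),
                           registry = NULL, file = NULL,
                           label = c("pef", "none"), min_length = 5) {
  method <- match.arg(method)
  label <- match.arg(label)
  if (method == "registry") {
    ann <- pef_registry(registry %||% "sorcin")
    ann$chain <- chain
    return(ann)
  }
  if (method == "file") {
    ann <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE)
    needed <- c("helix", "chain", "start", "end")
    if (!all(needed %in% names(ann))) {
      abort("annotation file needs columns: helix, chain, start, end")
    }
    return(as_tibble(ann[, needed]))
  }
  ca <- select_atoms(s, chain, atoms = "CA")
  ca <- ca[!ca$het, ]
  if (nrow(ca) < min_length) abort("too few resolved residues to assign helices")
  segs <- helical_segments(ca, min_length = min_length)
  if (nrow(segs) == 0) {
    abort("no helical segments found; supply annotations via registry or file mode")
  }
  segs$chain <- chain
  if (label == "none") {
    segs$helix <- paste0("seg", seq_len(nrow(segs)))
    return(segs[, c("helix", "chain", "start", "end")])
  }
  if (nrow(segs) < 8) {
    abort(sprintf(paste0("found %d helical segments but PEF labelling needs 8; ",
                         "use method = 'registry' or 'file'"), nrow(segs)))
  }
  keep <- order(segs$end - segs$start, decreasing = TRUE)[1:8]
  segs <- segs[sort(keep), ]
  segs$helix <- LETTERS[1:8]
  segs[, c("helix", "chain", "start", "end")]
}

helical_segments <- function(ca, min_length = 5) {
  m <- atom_coords(ca)
  n <- nrow(m)
  d_k <- function(k) {
    d <- rep(NA_real_, n)
    idx <- seq_len(n - k)
    # only meaningful between sequence-consecutive residues
    ok <- ca$res_id[idx + k] - ca$res_id[idx] == k
    d[idx[ok]] <- sqrt(rowSums((m[idx[ok] + k, , drop = FALSE] -
                                  m[idx[ok], , drop = FALSE])^2))
    d
  }
  d3 <- d_k(3); d4 <- d_k(4)
  helical <- !is.na(d3) & d3 >= 4.5 & d3 <= 5.6 &
    !is.na(d4) & d4 >= 5.6 & d4 <= 6.9
  # residue i starts a helical window covering i..i+4
  member <- rep(FALSE, n)
  for (i in which(helical)) member[i:min(n, i + 4)] <- TRUE
  # break runs where the author numbering is discontinuous
  block <- cumsum(c(1L, as.integer(diff(ca$res_id) != 1L)))
  run <- cumsum(c(1L, as.integer(diff(member) != 0L | diff(block) != 0L)))
  starts <- ends <- integer(0)
  for (r in unique(run)) {
    idx <- which(run == r)
    if (member[idx[1]] && length(idx) >= min_length) {
      starts <- c(starts, idx[1]); ends <- c(ends, idx[length(idx)])
    }
  }
  tibble(start = ca$res_id[starts], end = ca$res_id[ends])
}

#' Built-in helix registries for PEF proteins
#'
#' Approximate helix boundary tables for Sorcin, PDCD6/Alg-2 and the
#' calpain small-subunit dVI domain, following the canonical eight-helix
#' PEF architecture (helix A after the glycine-rich N-terminal domain, long
#' D and G helices shared between adjacent EF-hands). These tables are
#' synthetic conveniences, not measured from deposited coordinates: for any
#' real structure, derive exact boundaries with
#' `assign_helices(method = "auto")` or [derive_registry()], which is also
#' how apo/holo pairs should share one common registry.
#'
#' @param name `"sorcin"`, `"pdcd6"` or `"calpain_dvi"`.
#' @return A tibble: `helix`, `chain`, `start`, `end`.
#' @export
pef_registry <- function(name = c("sorcin", "pdcd6", "calpain_dvi")) {
  name <- match.arg(name)
  reg <- list(
    sorcin = tibble(
      helix = LETTERS[1:8],
      start = c(33L, 56L, 68L, 88L, 121L, 138L, 153L, 180L),
      end   = c(45L, 65L, 78L, 116L, 131L, 149L, 176L, 192L)),
    pdcd6 = tibble(
      helix = LETTERS[1:8],
      start = c(23L, 46L, 58L, 78L, 111L, 128L, 143L, 170L),
      end   = c(35L, 55L, 68L, 106L, 121L, 139L, 166L, 182L)),
    calpain_dvi = tibble(
      helix = LETTERS[1:8],
      start = c(95L, 118L, 130L, 150L, 183L, 200L, 215L, 242L),
      end   = c(107L, 127L, 140L, 178L, 193L, 211L, 238L, 254L)))[[name]]
  reg$chain <- "A"
  reg[, c("helix", "chain", "start", "end")]
}

#' Derive a reusable helix registry from a structure
#'
#' Runs the auto assigner and, when a second structure is given (an apo/holo
#' pair), trims every helix to the residue range resolved in both, so that
#' opening-angle differences measure conformational change rather than
#' boundary re-assignment.
#'
#' @param s A `pef_structure`.
#' @param chain Chain to annotate.
#' @param other Optional paired `pef_structure`.
#' @return A registry tibble: `helix`, `chain`, `start`, `end`.
#' @export
derive_registry <- function(s, chain, other = NULL) {
  ann <- assign_helices(s, chain, method = "auto")
  if (!is.null(other)) {
    res <- select_atoms(other, chain, atoms = "CA")
    ann$start <- pmax(ann$start, min(res$res_id))
    ann$end <- pmin(ann$end, max(res$res_id))
  }
  ann
}

#' EF-hand definitions for the PEF topology
#'
#' The five EF-hands in terms of their entering and exiting helices:
#' EF1 = A–B, EF2 = C–D, EF3 = D–E, EF4 = F–G, EF5 = G–H. The long D and G
#' helices are each shared by two hands.
#'
#' @return A tibble: `ef`, `entering`, `exiting`.
#' @export
efhand_defs <- function() {
  tibble(ef = paste0("EF", 1:5),
         entering = c("A", "C", "D", "F", "G"),
         exiting = c("B", "D", "E", "G", "H"))
}

#' EF-hand opening angles and the hD-hG sub-domain angle
#'
#' For each EF-hand, the opening angle theta is the angle between the
#' directed axes of its entering and exiting helices ([fit_helix_axis()],
#' [interhelix_angle()]). The angle between the long D and G helices is
#' reported as `hD-hG`: it tracks the movement of the EF1-EF2-EF3
#' sub-domain relative to the EF4-EF5 dimerisation sub-domain, the
#' global indicator of calcium activation in this family.
#'
#' @param s A `pef_structure`.
#' @param chain Chain to analyse.
#' @param annotations Helix annotation tibble from [assign_helices()].
#' @param ef_defs EF-hand definitions (default [efhand_defs()]).
#' @param label Row label for the report (defaults to the entry id).
#'
#' @return An angle report tibble: `label`, `angle` (`EF1`..`EF5`,
#'   `hD-hG`), `theta` (degrees, `[0, 180]`; `NA` when a helix is missing).
#' @export
efhand_angles <- function(s, chain, annotations, ef_defs = efhand_defs(),
                          label = NULL) {
  label <- label %||% attr(s, "entry_id") %||% "structure"
  axes <- helix_axes(s, chain, annotations)
  one <- function(h1, h2) {
    if (is.null(axes[[h1]]) || is.null(axes[[h2]])) return(NA_real_)
    interhelix_angle(axes[[h1]], axes[[h2]])
  }
  thetas <- purrr::map2_dbl(ef_defs$entering, ef_defs$exiting, one)
  tibble(label = label,
         angle = c(ef_defs$ef, "hD-hG"),
         theta = c(thetas, one("D", "G")))
}

helix_axes <- function(s, chain, annotations) {
  axes <- setNames(vector("list", nrow(annotations)), annotations$helix)
  for (i in seq_len(nrow(annotations))) {
    ca <- select_atoms(s, chain, annotations$start[i], annotations$end[i],
                       atoms = "CA")
    if (nrow(ca) >= 4) axes[[annotations$helix[i]]] <- fit_helix_axis(ca)
  }
  axes
}

#' Apo-to-holo opening-angle differences
#'
#' @param apo,holo Angle reports from [efhand_angles()] over the same
#'   angle set.
#' @return A tibble: `angle`, `theta_apo`, `theta_holo`,
#'   `delta` (= holo - apo, signed degrees), plus `apo`/`holo` labels.
#' @export
delta_table <- function(apo, holo) {
  if (!setequal(apo$angle, holo$angle)) {
    abort("apo and holo reports cover different angle sets")
  }
  out <- inner_join(rename(apo, theta_apo = "theta"),
                    rename(select(holo, -"label"), theta_holo = "theta"),
                    by = "angle")
  out |>
    mutate(apo = .data$label, holo = holo$label[1],
           delta = .data$theta_holo - .data$theta_apo) |>
    select("apo", "holo", "angle", "theta_apo", "theta_holo", "delta")
}

#' Family-wide angle comparison table
#'
#' One angle report per entry plus delta rows for declared apo/holo pairs;
#' the shape of the classic PEF comparison table (one row per structure,
#' one column per EF-hand plus hD-hG).
#'
#' @param entries A list of entries, each a list with `label`,
#'   `structure`, `chain` and `annotations`.
#' @param pairs Optional data frame with columns `apo`, `holo` naming entry
#'   labels to difference.
#'
#' @return A list with `angles` (wide tibble, one row per entry) and
#'   `deltas` (one row per pair per angle).
#' @export
compare_family <- function(entries, pairs = NULL) {
  labels <- vapply(entries, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("duplicate entry labels in family table")
  reports <- lapply(entries, function(e) {
    efhand_angles(e$structure, e$chain, e$annotations, label = e$label)
  })
  names(reports) <- labels
  angles <- bind_rows(reports) |>
    tidyr::pivot_wider(names_from = "angle", values_from = "theta")
  deltas <- NULL
  if (!is.null(pairs)) {
    pairs <- as_tibble(pairs)
    missing <- setdiff(c(pairs$apo, pairs$holo), labels)
    if (length(missing) > 0) {
      abort(paste0("pair labels not in entries: ", paste(missing, collapse = ", ")))
    }
    deltas <- purrr::map2_dfr(pairs$apo, pairs$holo, function(a, h) {
      delta_table(reports[[a]], reports[[h]])
    })
  }
  list(angles = angles, deltas = deltas)
}
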