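#' Detect bound metal ions and their coordination spheres
#'
#' Every hetero atom of the requested element becomes a candidate site; its
#' ligands are the oxygen and nitrogen atoms (protein side chain, protein
#' backbone, or water) within the distance cutoff, other metals excluded.
#' The default 2.9 angstrom cutoff covers the canonical 2.3-2.6 angstrom
#' Ca-O range plus the longer reach of bidentate carboxylates (each
#' carboxylate oxygen counts as a separate ligand, which is how an EF-hand
#' glutamate contributes two of the seven coordinating atoms). When a helix
#' annotation table is supplied, each site is tagged with the EF-hand whose
#' inter-helix loop contains it.
#'
#' @param s A `pef_structure`.
#' @param element Metal element symbol (default `"CA"`, calcium).
#' @param cutoff Metal-ligand distance cutoff in angstrom, in (0, 4].
#' @param annotations Optional helix annotation tibble for EF-hand tagging.
#' @param ef_defs EF-hand definitions (default [efhand_defs()]).
#'
#' @return A tibble with one row per site: metal identifiers, `n_ligands`,
#'   `geometry`, `deviation` (degrees), `ef_hand`, and a `ligands` list
#'   column (tibble of ligand atoms with `distance` and `source`).
#'   Zero rows when the element is absent.
#' @export
find_metal_sites <- function(s, element = "CA", cutoff = 2.9,
                             annotations = NULL, ef_defs = efhand_defs()) {
  if (cutoff <= 0 || cutoff > 4) abort("cutoff must be in (0, 4] angstrom")
  metals <- s[s$het & s$element == toupper(element), ]
  if (nrow(metals) == 0) return(empty_site_table())
  metal_idx <- which(s$het & s$element %in%
                       c("CA", "ZN", "MG", "MN", "FE", "NA", "K", "CU", "NI") &
                       s$res_name != "HOH")
  cand <- s[setdiff(which(s$element %in% c("O", "N")), metal_idx), ]
  sites <- purrr::map_dfr(seq_len(nrow(metals)), function(i) {
    met <- metals[i, ]
    d <- outer_dist(atom_coords(met), atom_coords(cand))[1, ]
    lig_full <- as_tibble(cand[d <= cutoff, ])
    lig_full$distance <- d[d <= cutoff]
    geom <- classify_geometry(atom_coords(met)[1, ], atom_coords(lig_full))
    lig <- lig_full |>
      mutate(source = dplyr::case_when(
        .data$res_name %in% c("HOH", "WAT") ~ "water",
        .data$atom_name %in% c("N", "O", "C", "CA", "OXT") ~ "backbone",
        TRUE ~ "side-chain")) |>
      select("chain", "res_id", "res_name", "atom_name", "element",
             "distance", "source") |>
      arrange(.data$distance)
    tibble(metal_chain = met$chain, metal_res_id = met$res_id,
           metal_name = met$res_name, element = met$element,
           n_ligands = nrow(lig),
           geometry = geom$geometry, deviation = geom$deviation,
           ef_hand = tag_ef_hand(met$res_id, metals$chain[i], lig,
                                 annotations, ef_defs),
           ligands = list(lig))
  })
  sites
}

tag_ef_hand <- function(metal_res, metal_chain, lig, annotations, ef_defs) {
  if (is.null(annotations)) return(NA_character_)
  prot <- lig[lig$source != "water", ]
  if (nrow(prot) == 0) return(NA_character_)
  mid <- stats::median(prot$res_id)
  # the calcium loop lies between the entering and exiting helices
  for (k in seq_len(nrow(ef_defs))) {
    ent <- annotations[annotations$helix == ef_defs$entering[k], ]
    ext <- annotations[annotations$helix == ef_defs$exiting[k], ]
    if (nrow(ent) == 1 && nrow(ext) == 1 &&
        mid >= ent$start && mid <= ext$end) {
      return(ef_defs$ef[k])
    }
  }
  NA_character_
}

empty_site_table <- function() {
  tibble(metal_chain = character(), metal_res_id = integer(),
         metal_name = character(), element = character(),
         n_ligands = integer(), geometry = character(),
         deviation = double(), ef_hand = character(), ligands = list())
}

#' Classify a coordination sphere against ideal polyhedra
#'
#' For seven ligands the pentagonal-bipyramidal (PBP) template is tested:
#' every one of the C(7,2) = 21 ligand pairs is tried as the axial pair
#' (exhaustive, no heuristics), the remaining five are ordered by azimuth
#' about the axial axis, and the deviation is the mean absolute angular
#' residual against the ideal angles (axial-axial 180 degrees,
#' axial-equatorial 90, adjacent equatorial 72). For six ligands the
#' octahedral template is tested the same way (all inter-ligand angles
#' ideally 90 or 180). The class is assigned when the best deviation falls
#' below `threshold`.
#'
#' @param center Metal coordinates (3-vector).
#' @param ligand_coords n x 3 matrix of ligand coordinates.
#' @param threshold Classification threshold in degrees (default 20).
#'
#' @return A list: `geometry` (`"pentagonal_bipyramidal"`, `"octahedral"`
#'   or `"other"`) and `deviation` (mean absolute angular residual in
#'   degrees; `NA` for fewer than 4 ligands).
#' @export
classify_geometry <- function(center, ligand_coords, threshold = 20) {
  m <- as_coord_matrix(ligand_coords)
  n <- nrow(m)
  if (n < 4) return(list(geometry = "other", deviation = NA_real_))
  u <- sweep(m, 2, as.numeric(center))
  u <- u / sqrt(rowSums(u^2))
  if (n == 7) {
    dev <- pbp_deviation(u)
    return(list(geometry = if (dev < threshold) "pentagonal_bipyramidal" else "other",
                deviation = dev))
  }
  if (n == 6) {
    dev <- octahedral_deviation(u)
    return(list(geometry = if (dev < threshold) "octahedral" else "other",
                deviation = dev))
  }
  # no template for this coordination number; report the best of both
  # neighbouring templates as a descriptive deviation
  list(geometry = "other", deviation = best_partial_deviation(u))
}

pair_angle <- function(u, i, j) {
  d <- max(-1, min(1, sum(u[i, ] * u[j, ])))
  acos(d) * 180 / pi
}

pbp_deviation <- function(u) {
  n <- nrow(u)
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ax <- c(i, j)
    eq <- setdiff(seq_len(n), ax)
    axis <- u[i, ] - u[j, ]
    axis <- axis / sqrt(sum(axis^2))
    resid <- abs(pair_angle(u, i, j) - 180)
    # axial-equatorial
    for (e in eq) {
      resid <- c(resid, abs(pair_angle(u, i, e) - 90),
                 abs(pair_angle(u, j, e) - 90))
    }
    # adjacent equatorial spacing about the axial axis
    basis <- orthonormal_basis(axis)
    az <- atan2(u[eq, , drop = FALSE] %*% basis[, 2],
                u[eq, , drop = FALSE] %*% basis[, 1])
    az <- sort(as.numeric(az))
    gaps <- diff(c(az, az[1] + 2 * pi)) * 180 / pi
    resid <- c(resid, abs(gaps - 72))
    dev <- mean(resid)
    if (dev < best) best <- dev
  }
  best
}

octahedral_deviation <- function(u) {
  n <- nrow(u)
  resid <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- pair_angle(u, i, j)
    resid <- c(resid, min(abs(a - 90), abs(a - 180)))
  }
  mean(resid)
}

best_partial_deviation <- function(u) {
  n <- nrow(u)
  resid <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- pair_angle(u, i, j)
    resid <- c(resid, min(abs(a - 72), abs(a - 90), abs(a - 144), abs(a - 180)))
  }
  mean(resid)
}

orthonormal_basis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cbind(e1, e2)
}
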