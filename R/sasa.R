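#' Van der Waals radii used for surface calculations
#'
#' Bondi-style heavy-atom radii (angstrom): C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, H 1.20, Se 1.90; 1.70 for anything else. Recorded in every SASA
#' profile for provenance.
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of radii.
#' @export
vdw_radius <- function(elements) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
           SE = 1.90, CA = 2.31, ZN = 1.39, MG = 1.73)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the structure by point sampling: each atom is
#' expanded to radius r + probe, covered with a deterministic quasi-uniform
#' point lattice, and the accessible fraction is the share of points not
#' occluded by any neighbouring expanded sphere. Waters and hetero atoms
#' (ions, ligands) are excluded from both the surface and the occluders by
#' default, the usual convention for protein-surface analysis.
#'
#' @param s A `pef_structure`.
#' @param probe Probe radius in angstrom (default 1.4, water).
#' @param n_points Sample points per atom (default 960; >= 100).
#' @param include_het Keep non-water hetero atoms (ions, ligand chains).
#' @param include_waters Keep waters.
#'
#' @return A `pef_sasa` tibble keyed by (`chain`, `res_id`): per-residue
#'   `sasa` in square angstrom, with the per-atom table in
#'   `attr(, "atom_sasa")` and the sampling parameters in
#'   `attr(, "params")`.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960,
                         include_het = FALSE, include_waters = FALSE) {
  if (probe <= 0) abort("probe radius must be positive")
  if (n_points < 100) abort("n_points must be >= 100")
  a <- as_tibble(s)
  if (!include_waters) a <- a[!a$res_name %in% c("HOH", "WAT"), ]
  if (!include_het) a <- a[!a$het | a$res_name %in% c("HOH", "WAT"), , drop = FALSE]
  if (nrow(a) == 0) abort("no atoms left after filtering; empty structure?")
  coords <- atom_coords(a)
  rad <- vdw_radius(a$element) + probe
  pts <- sphere_points(n_points)
  n <- nrow(a)
  area <- numeric(n)
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    nb <- which(d < rad[i] + maxr & d > 0)
    nb <- nb[d[nb] < rad[i] + rad[nb]]
    if (length(nb) == 0) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- sweep(pts * rad[i], 2, coords[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      free <- free & dj2 > rad[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  a$sasa <- area
  res <- a |>
    group_by(.data$chain, .data$res_id, .data$res_name) |>
    summarise(sasa = sum(.data$sasa), .groups = "drop")
  structure(res,
            class = c("pef_sasa", class(tibble())),
            atom_sasa = a,
            params = list(probe = probe, n_points = n_points,
                          radii = "bondi-heavy",
                          include_het = include_het,
                          include_waters = include_waters))
}

#' Apo-to-holo exposure changes with percentage-threshold flagging
#'
#' The relative change is `100 * (holo - apo) / max(apo, 1)` per residue
#' (the 1 square-angstrom denominator floor keeps near-buried residues from
#' producing unbounded percentages). A residue is flagged when its relative
#' change exceeds `threshold` percent AND its absolute increase is at least
#' `min_abs` square angstrom, i.e. flagging targets genuine increases in
#' exposed surface, the signature of an opening conformational change.
#'
#' @param apo,holo `pef_sasa` profiles sharing residue keys.
#' @param threshold Relative-change threshold in percent (default 30).
#' @param min_abs Absolute-increase guard in square angstrom (default 5).
#'
#' @return A tibble: residue keys, `sasa_apo`, `sasa_holo`,
#'   `relative_change` (percent), `flagged`.
#' @export
delta_sasa <- function(apo, holo, threshold = 30, min_abs = 5) {
  if (threshold <= 0) abort("threshold must be positive")
  out <- inner_join(rename(as_tibble(apo), sasa_apo = "sasa"),
                    rename(as_tibble(holo), sasa_holo = "sasa"),
                    by = c("chain", "res_id", "res_name"))
  if (nrow(out) == 0) abort("profiles share no residues")
  out |>
    mutate(relative_change = 100 * (.data$sasa_holo - .data$sasa_apo) /
             pmax(.data$sasa_apo, 1),
           flagged = .data$relative_change > threshold &
             (.data$sasa_holo - .data$sasa_apo) >= min_abs)
}

# theoretical maximum per-residue SASA in a Gly-X-Gly tripeptide
# (Tien et al. 2013, theoretical column), square angstrom
gxg_reference <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)

hydrophobic_set <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                     "TYR", "PRO")

#' Solvent-exposed hydrophobic surface patches
#'
#' A simplified hydrophobic-patch detector in the spirit of Hotpatch-style
#' servers ("Hotpatch-like"; the original server's statistical model is not
#' reproduced). Hydrophobic residues (A, V, L, I, M, F, W, Y, P) count as
#' exposed when their SASA reaches `min_rel_sasa` percent of the Gly-X-Gly
#' reference maximum; exposed residues are clustered by single linkage on
#' side-chain centroid distances and clusters are ranked by total exposed
#' area. Singleton clusters are dropped.
#'
#' @param s A `pef_structure`.
#' @param sasa A matching `pef_sasa` profile.
#' @param linkage Single-linkage distance cutoff between side-chain
#'   centroids, angstrom (default 6.5).
#' @param min_rel_sasa Relative-exposure criterion in percent (default 20).
#'
#' @return A tibble ranked by `total_exposed_area`: `patch` (rank),
#'   `n_residues`, `total_exposed_area`, `hydrophobic_fraction` and a
#'   `members` list column (residues with their SASA).
#' @export
hydrophobic_patches <- function(s, sasa, linkage = 6.5, min_rel_sasa = 20) {
  if (linkage <= 0) abort("linkage must be positive")
  prof <- as_tibble(sasa)
  prof <- prof[prof$res_name %in% hydrophobic_set, ]
  prof$rel <- 100 * prof$sasa / gxg_reference[prof$res_name]
  prof <- prof[prof$rel >= min_rel_sasa, ]
  if (nrow(prof) < 2) return(empty_patch_table())
  cent <- purrr::map_dfr(seq_len(nrow(prof)), function(i) {
    res <- s[s$chain == prof$chain[i] & s$res_id == prof$res_id[i], ]
    side <- res[!res$atom_name %in% c("N", "C", "O", "OXT") &
                  res$element != "H", ]
    if (nrow(side) == 0) side <- res
    m <- colMeans(atom_coords(side))
    tibble(x = m[1], y = m[2], z = m[3])
  })
  d <- dist(as.matrix(cent))
  cl <- if (nrow(prof) == 2) {
    if (as.numeric(d)[1] <= linkage) c(1L, 1L) else c(1L, 2L)
  } else {
    cutree(hclust(d, method = "single"), h = linkage)
  }
  prof$cluster <- cl
  patches <- prof |>
    group_by(.data$cluster) |>
    summarise(n_residues = n(),
              total_exposed_area = sum(.data$sasa),
              hydrophobic_fraction = 1,
              members = list(dplyr::pick("chain", "res_id", "res_name", "sasa")),
              .groups = "drop") |>
    filter(.data$n_residues > 1) |>
    arrange(dplyr::desc(.data$total_exposed_area)) |>
    mutate(patch = row_number()) |>
    select("patch", "n_residues", "total_exposed_area",
           "hydrophobic_fraction", "members")
  patches
}

empty_patch_table <- function() {
  tibble(patch = integer(), n_residues = integer(),
         total_exposed_area = double(), hydrophobic_fraction = double(),
         members = list())
}

#' Residues buried at a two-partner interface
#'
#' SASA is computed for the complex and for each partner in isolation; a
#' residue is buried when its isolated-minus-complex SASA reaches
#' `min_burial`. The total buried area is the sum over both partners (so
#' twice the geometric contact area).
#'
#' @param s A `pef_structure` containing both partners.
#' @param chains_a,chains_b Disjoint chain sets defining the partners.
#' @param min_burial Minimum per-residue burial in square angstrom
#'   (default 1).
#' @param probe,n_points Passed to [compute_sasa()].
#' @param include_het Treat hetero (e.g. peptide HETATM) records as part of
#'   the partners (default `TRUE`: ligand peptides are often deposited as
#'   hetero chains).
#'
#' @return A tibble of buried residues: `partner`, residue keys,
#'   `sasa_isolated`, `sasa_complex`, `burial`; total buried area in
#'   `attr(, "total_buried")`.
#' @export
interface_burial <- function(s, chains_a, chains_b, min_burial = 1,
                             probe = 1.4, n_points = 960, include_het = TRUE) {
  if (length(intersect(chains_a, chains_b)) > 0) {
    abort("partner chain sets overlap")
  }
  missing <- setdiff(c(chains_a, chains_b), unique(s$chain))
  if (length(missing) > 0) {
    abort(paste0("chain(s) not in structure: ", paste(missing, collapse = ", ")))
  }
  sub <- function(chains) {
    new_structure(as_tibble(s)[s$chain %in% chains &
                                 !s$res_name %in% c("HOH", "WAT"), ],
                  entry_id = attr(s, "entry_id"))
  }
  both <- compute_sasa(sub(c(chains_a, chains_b)), probe, n_points,
                       include_het = include_het)
  iso <- bind_rows(
    mutate(as_tibble(compute_sasa(sub(chains_a), probe, n_points,
                                  include_het = include_het)), partner = "a"),
    mutate(as_tibble(compute_sasa(sub(chains_b), probe, n_points,
                                  include_het = include_het)), partner = "b"))
  out <- iso |>
    rename(sasa_isolated = "sasa") |>
    inner_join(rename(as_tibble(both), sasa_complex = "sasa"),
               by = c("chain", "res_id", "res_name")) |>
    mutate(burial = .data$sasa_isolated - .data$sasa_complex) |>
    filter(.data$burial >= min_burial) |>
    arrange(dplyr::desc(.data$burial)) |>
    select("partner", "chain", "res_id", "res_name",
           "sasa_isolated", "sasa_complex", "burial")
  structure(out, total_buried = sum(out$burial))
}
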