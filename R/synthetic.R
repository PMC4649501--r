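#' Build an ideal alpha-helix C-alpha trace
#'
#' Canonical alpha-helix C-alpha geometry: 1.5 angstrom rise and 100 degree
#' twist per residue on a 2.3 angstrom radius, giving the familiar 3.8
#' angstrom consecutive C-alpha spacing and 5.4 angstrom pitch. The helix
#' axis is exactly `axis_direction` through `origin`, oriented N- to
#' C-terminus.
#'
#' @param n_residues Number of residues (>= 4).
#' @param rise Rise per residue, angstrom.
#' @param twist Twist per residue, degrees.
#' @param radius Helix radius, angstrom.
#' @param axis_direction Axis direction (3-vector, normalised internally).
#' @param origin Axis origin.
#' @param chain Chain identifier.
#' @param res_start First author residue number.
#' @param phase Azimuthal phase of the first residue, degrees.
#'
#' @return A `pef_structure` of poly-alanine C-alpha atoms.
#' @export
build_helix <- function(n_residues = 12, rise = 1.5, twist = 100,
                        radius = 2.3, axis_direction = c(0, 0, 1),
                        origin = c(0, 0, 0), chain = "A", res_start = 1L,
                        phase = 0) {
  if (n_residues < 4) abort("a helix needs at least 4 residues")
  i <- seq_len(n_residues) - 1
  ang <- (phase + twist * i) * pi / 180
  local <- cbind(radius * cos(ang), radius * sin(ang), rise * i)
  R <- rotation_to(c(0, 0, 1), axis_direction)
  xyz <- sweep(local %*% t(R), 2, as.numeric(origin), `+`)
  new_structure(tibble(
    chain = chain, res_id = res_start + i, ins = "", res_name = "ALA",
    atom_name = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, b = 0, het = FALSE),
    entry_id = "SYNTH-HELIX")
}

# rotation carrying unit vector a onto unit vector b
rotation_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_matrix(pracma_cross(a, perp), 180))
  }
  rotation_matrix(v / s, acos(max(-1, min(1, cth))) * 180 / pi)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# unit vector at a prescribed angle from v, azimuth chosen deterministically
# (or by the active RNG when random = TRUE)
vector_at_angle <- function(v, angle_deg, azimuth_deg = 0) {
  v <- v / sqrt(sum(v^2))
  basis <- orthonormal_basis(v)
  w <- cos(azimuth_deg * pi / 180) * basis[, 1] +
    sin(azimuth_deg * pi / 180) * basis[, 2]
  th <- angle_deg * pi / 180
  cos(th) * v + sin(th) * w
}

#' Build an apo/holo pair of two-helix EF-hand models
#'
#' Two synthetic structures sharing the entering helix (A, along +z), with
#' the exiting helix (B) built at the prescribed opening angles. The
#' returned annotation table and EF-hand definition make the pair directly
#' consumable by [efhand_angles()] / [delta_table()], so a planted apo-to-
#' holo opening is recovered end to end through the measurement code path.
#'
#' @param theta_apo,theta_holo Opening angles in degrees, in (0, 180).
#' @param n_residues Residues per helix.
#'
#' @return A list: `apo`, `holo` (`pef_structure`s), `annotations`
#'   (helix table) and `ef_defs` (single EF1 row).
#' @export
build_efhand_pair <- function(theta_apo, theta_holo, n_residues = 12) {
  stopifnot(theta_apo > 0, theta_apo < 180, theta_holo > 0, theta_holo < 180)
  one <- function(theta) {
    hA <- build_helix(n_residues, res_start = 1L)
    dirB <- vector_at_angle(c(0, 0, 1), theta)
    hB <- build_helix(n_residues, axis_direction = dirB,
                      origin = c(8, 0, 1.5 * n_residues + 4),
                      res_start = n_residues + 5L)
    s <- bind_structures(hA, hB, entry_id = sprintf("SYNTH-EF-%.1f", theta))
    s
  }
  ann <- tibble(helix = c("A", "B"), chain = "A",
                start = c(1L, n_residues + 5L),
                end = c(n_residues, 2L * n_residues + 4L))
  list(apo = one(theta_apo), holo = one(theta_holo), annotations = ann,
       ef_defs = tibble(ef = "EF1", entering = "A", exiting = "B"))
}

#' Build a synthetic eight-helix PEF monomer at prescribed angles
#'
#' Constructs ideal helices A-H whose directed axes satisfy a full set of
#' PEF opening angles: EF1 (A-B), EF2 (C-D), EF3 (D-E), EF4 (F-G),
#' EF5 (G-H) and the hD-hG sub-domain angle. Helix D is the reference
#' direction; C, E and G are placed at the EF2, EF3 and hD-hG angles from
#' it, F and H at the EF4/EF5 angles from G, and B at the EF1 angle from a
#' freely chosen A. Azimuths are drawn reproducibly under `seed`, so the
#' same angle set yields many distinct geometries. This is the synthetic
#' stand-in used to exercise the full angle pipeline when deposited
#' structures are unavailable.
#'
#' @param angles Named numeric vector with entries `EF1`..`EF5` and
#'   `hD-hG`, degrees.
#' @param n_residues Residues per helix.
#' @param seed Integer seed for the azimuth draws.
#'
#' @return A list: `structure` (a `pef_structure` with helices in
#'   sequence order A..H) and `annotations`.
#' @export
build_pef_monomer <- function(angles, n_residues = 12, seed = 1) {
  needed <- c("EF1", "EF2", "EF3", "EF4", "EF5", "hD-hG")
  if (!all(needed %in% names(angles))) {
    abort(paste0("angles must name: ", paste(needed, collapse = ", ")))
  }
  dirs <- withr::with_seed(seed, {
    az <- function() runif(1, 0, 360)
    dD <- c(0, 0, 1)
    dC <- vector_at_angle(dD, angles[["EF2"]], az())
    dE <- vector_at_angle(dD, angles[["EF3"]], az())
    dG <- vector_at_angle(dD, angles[["hD-hG"]], az())
    dF <- vector_at_angle(dG, angles[["EF4"]], az())
    dH <- vector_at_angle(dG, angles[["EF5"]], az())
    dA <- vector_at_angle(dD, 30, az())
    dB <- vector_at_angle(dA, angles[["EF1"]], az())
    list(A = dA, B = dB, C = dC, D = dD, E = dE, F = dF, G = dG, H = dH)
  })
  offs <- 22 * cbind(c(0, 1, 2, 3, 0, 1, 2, 3), c(0, 0, 0, 0, 1, 1, 1, 1), 0)
  helices <- purrr::imap(dirs, function(d, nm) {
    k <- match(nm, LETTERS[1:8])
    build_helix(n_residues, axis_direction = d, origin = offs[k, ],
                res_start = (k - 1L) * (n_residues + 8L) + 1L)
  })
  s <- do.call(bind_structures, c(unname(helices), list(entry_id = "SYNTH-PEF")))
  ann <- tibble(helix = LETTERS[1:8], chain = "A",
                start = (0:7) * (n_residues + 8L) + 1L,
                end = (0:7) * (n_residues + 8L) + n_residues)
  list(structure = s, annotations = ann)
}

#' Build an ideal metal coordination site
#'
#' One calcium hetero atom surrounded by oxygen pseudo-ligands (modelled as
#' water oxygens) in an ideal pentagonal-bipyramidal (2 axial + 5
#' equatorial at 72 degree spacing) or octahedral arrangement, with
#' optional angular jitter applied reproducibly under `seed`.
#'
#' @param geometry `"pentagonal_bipyramidal"` or `"octahedral"`.
#' @param bond_length Metal-ligand distance, angstrom.
#' @param angular_jitter_sd Gaussian angular displacement of each ligand,
#'   degrees.
#' @param seed Seed for the jitter.
#' @param center Metal position.
#' @param chain Chain id for the site.
#' @param res_start Author residue number of the metal (ligands follow).
#'
#' @return A `pef_structure` (all hetero records).
#' @export
build_metal_site <- function(geometry = c("pentagonal_bipyramidal", "octahedral"),
                             bond_length = 2.4, angular_jitter_sd = 0,
                             seed = NULL, center = c(0, 0, 0), chain = "M",
                             res_start = 500L) {
  geometry <- match.arg(geometry)
  dirs <- if (geometry == "pentagonal_bipyramidal") {
    eq <- t(vapply(72 * (0:4) * pi / 180,
                   function(a) c(cos(a), sin(a), 0), numeric(3)))
    rbind(c(0, 0, 1), c(0, 0, -1), eq)
  } else {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  }
  jitter_one <- function(u) {
    if (angular_jitter_sd <= 0) return(u)
    basis <- orthonormal_basis(u)
    ax <- cos(runif(1, 0, 2 * pi)) * basis[, 1] +
      sin(runif(1, 0, 2 * pi)) * basis[, 2]
    as.numeric(rotation_matrix(ax, rnorm(1, 0, angular_jitter_sd)) %*% u)
  }
  apply_jitter <- function() t(apply(dirs, 1, jitter_one))
  dirs <- if (!is.null(seed)) withr::with_seed(seed, apply_jitter())
  else apply_jitter()
  lig <- sweep(dirs * bond_length, 2, as.numeric(center), `+`)
  atoms <- bind_rows(
    tibble(chain = chain, res_id = res_start, ins = "", res_name = "CA",
           atom_name = "CA", element = "CA",
           x = center[1], y = center[2], z = center[3],
           occ = 1, b = 0, het = TRUE),
    tibble(chain = chain, res_id = res_start + seq_len(nrow(lig)), ins = "",
           res_name = "HOH", atom_name = "O", element = "O",
           x = lig[, 1], y = lig[, 2], z = lig[, 3],
           occ = 1, b = 0, het = TRUE))
  new_structure(atoms, entry_id = paste0("SYNTH-", toupper(geometry)))
}

#' Generate a motif-planted phage-display-style peptide set
#'
#' Emulates the output of a peptide phage-display selection: `n` peptides
#' of the library's display length (16 by default), a `prevalence` fraction
#' of which carry one instance of the planted motif at a uniformly random
#' offset, all remaining positions drawn from the background composition.
#'
#' @param n Number of peptides.
#' @param length Peptide length (>= motif length).
#' @param pattern A `pef_motif` to plant.
#' @param prevalence Fraction of peptides carrying the motif, in [0, 1].
#' @param background Named amino-acid frequency vector over the 20-letter
#'   alphabet (default uniform); normalised internally.
#' @param seed Integer seed.
#'
#' @return A tibble: `sequence`, `planted` (logical).
#' @export
generate_peptides <- function(n, length = 16, pattern = builtin_patterns()$phi_gm_x_p,
                              prevalence = 0.5, background = NULL, seed = 1) {
  L <- base::length(pattern$positions)
  if (L > length) abort("pattern longer than peptide length")
  if (prevalence < 0 || prevalence > 1) abort("prevalence must be in [0, 1]")
  bg <- background %||% setNames(rep(1 / 20, 20), AA_ALPHABET)
  bg <- bg[AA_ALPHABET]
  bg[is.na(bg)] <- 0
  if (sum(bg) <= 0) abort("background frequencies sum to zero")
  bg <- bg / sum(bg)
  withr::with_seed(seed, {
    planted <- seq_len(n) <= round(n * prevalence)
    seqs <- vapply(seq_len(n), function(i) {
      ch <- sample(AA_ALPHABET, length, replace = TRUE, prob = bg)
      if (planted[i]) {
        off <- sample.int(length - L + 1, 1)
        for (k in seq_len(L)) {
          ch[off + k - 1] <- sample(pattern$positions[[k]], 1)
        }
      }
      paste(ch, collapse = "")
    }, character(1))
    tibble(sequence = seqs, planted = planted)[sample.int(n), ]
  })
}
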