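# Published opening-angle sets for the PEF family (degrees), used as
# generator parameters for synthetic stand-in structures.
sorcin_apo_angles <- c(EF1 = 40.8, EF2 = 60.7, EF3 = 52, EF4 = 47.3,
                       EF5 = 32.9, `hD-hG` = 57.5)
sorcin_holo_angles <- c(EF1 = 59.2, EF2 = 57.9, EF3 = 66.5, EF4 = 45.9,
                        EF5 = 29.9, `hD-hG` = 78.1)
pdcd6_apo_angles <- c(EF1 = 68.8, EF2 = 51.5, EF3 = 59.2, EF4 = 56.5,
                      EF5 = 35.8, `hD-hG` = 80.2)
pdcd6_holo_angles <- c(EF1 = 72, EF2 = 52.6, EF3 = 64, EF4 = 58.4,
                       EF5 = 27.2, `hD-hG` = 82.2)
calpain_apo_angles <- c(EF1 = 40.3, EF2 = 53.6, EF3 = 30, EF4 = 51.5,
                        EF5 = 28, `hD-hG` = 47)
calpain_holo_angles <- c(EF1 = 61, EF2 = 63, EF3 = 46.2, EF4 = 49.4,
                         EF5 = 23.4, `hD-hG` = 52.3)

# measure all angles of a synthetic monomer through the standard pipeline
measure_monomer <- function(angles, seed, label = "x") {
  m <- build_pef_monomer(angles, seed = seed)
  efhand_angles(m$structure, "A", m$annotations, label = label)
}

# a single-atom 'residue' for coarse SASA/interface fixtures
atom_res <- function(chain, res_id, x, y = 0, z = 0, res_name = "LEU",
                     atom_name = "CB", element = "C", het = FALSE) {
  tibble::tibble(chain = chain, res_id = as.integer(res_id), ins = "",
                 res_name = res_name, atom_name = atom_name,
                 element = element, x = x, y = y, z = z,
                 occ = 1, b = 0, het = het)
}

# synthetic stand-in for a peptide bound in the hydrophobic groove, with
# hydrogen-bond distances planted at the published values (2.78 and 2.90 A)
build_peptide_interface_fixture <- function() {
  atoms <- dplyr::bind_rows(
    atom_res("A", 97, 0, 0, -4, res_name = "GLU", atom_name = "CA"),
    atom_res("A", 97, 0, 0, 0, res_name = "GLU", atom_name = "OE2",
             element = "O"),
    atom_res("A", 105, 20, 0, 0, res_name = "TRP", atom_name = "NE1",
             element = "N"),
    atom_res("P", 13, 2.78, 0, 0, res_name = "TYR", atom_name = "OH",
             element = "O"),
    atom_res("P", 13, 4.5, -3, 0, res_name = "TYR", atom_name = "O",
             element = "O"),
    atom_res("P", 14, 0, 2.90, 0, res_name = "TYR", atom_name = "O",
             element = "O"),
    atom_res("P", 15, 8, 8, 8, res_name = "PRO", atom_name = "CA"))
  new_structure(atoms, entry_id = "SYNTH-PEPTIDE-IFACE")
}

# apo/holo pair in which a planted residue set gains exposure: each target
# residue sits 2.2 A from a bulky occluder in the apo form and 9 A away in
# the holo form; decoy residues never move.
build_exposure_pair <- function(target_ids = c(67, 80, 81, 86, 110, 116,
                                               118, 143, 197),
                                decoy_ids = c(40, 55, 70, 125, 150, 180)) {
  ids <- sort(c(target_ids, decoy_ids))
  place <- function(holo) {
    purrr::map_dfr(seq_along(ids), function(k) {
      id <- ids[k]
      gap <- if (holo && id %in% target_ids) 9 else 2.2
      dplyr::bind_rows(
        atom_res("A", id, 40 * k, res_name = "SER", atom_name = "OG",
                 element = "O"),
        atom_res("X", 300L + k, 40 * k + gap, res_name = "PHE",
                 atom_name = "CZ"))
    })
  }
  list(apo = new_structure(place(FALSE), entry_id = "SYNTH-APO-EXPOSURE"),
       holo = new_structure(place(TRUE), entry_id = "SYNTH-HOLO-EXPOSURE"),
       targets = target_ids)
}

# three ideal pentagonal-bipyramidal calcium sites in one model, the
# stand-in for a calcium-loaded PEF monomer's EF1-EF3 sites
build_three_site_fixture <- function(jitter = 0, seed = NULL) {
  s1 <- build_metal_site("pentagonal_bipyramidal", angular_jitter_sd = jitter,
                         seed = seed, center = c(0, 0, 0), res_start = 500L)
  s2 <- build_metal_site("pentagonal_bipyramidal", angular_jitter_sd = jitter,
                         seed = if (is.null(seed)) NULL else seed + 1,
                         center = c(25, 0, 0), res_start = 600L)
  s3 <- build_metal_site("pentagonal_bipyramidal", angular_jitter_sd = jitter,
                         seed = if (is.null(seed)) NULL else seed + 2,
                         center = c(0, 25, 0), res_start = 700L)
  bind_structures(s1, s2, s3, entry_id = "SYNTH-3CA")
}

# naive window-by-window motif scan, the independent oracle for scan_motif
brute_force_scan <- function(seq, pattern) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(pattern$positions)
  hits <- integer(0)
  if (length(chars) >= L) {
    for (s in 1:(length(chars) - L + 1)) {
      ok <- TRUE
      for (k in 1:L) {
        if (!chars[s + k - 1] %in% pattern$positions[[k]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}

# random rigid transform under the current RNG
random_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  list(R = rotation_matrix(ax, runif(1, 0, 360)), t = rnorm(3, sd = 20))
}

transform_structure <- function(s, R, t) {
  xyz <- atom_coords(s) %*% t(R)
  s$x <- xyz[, 1] + t[1]; s$y <- xyz[, 2] + t[2]; s$z <- xyz[, 3] + t[3]
  s
}
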