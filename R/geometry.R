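#' Fit a helix axis to an ordered C-alpha trace
#'
#' The primary estimator uses the local curvature of the trace: for an
#' alpha-helix the second-difference vectors
#' `s_i = p_(i+1) - 2 p_i + p_(i-1)` point from the trace towards the axis,
#' so the cross product of consecutive second differences lies exactly
#' along the axis of an ideal helix; these cross products are averaged over
#' the whole trace, which makes the estimate robust to local irregularity
#' and exact (to machine precision) on regular helices. The sign is fixed
#' to point from the first (N-terminal) towards the last (C-terminal)
#' residue, so inter-helix angles between directed axes carry a consistent
#' opening sign. When the trace is too short or (near-)collinear the
#' estimator falls back to the first principal component of the point
#' cloud. On regular helices the result agrees with rendering-package axis
#' measures (e.g. PyMOL) to within a degree or two.
#'
#' @param ca_coords An n x 3 matrix (or data frame with x, y, z) of
#'   consecutive C-alpha coordinates, n >= 4.
#'
#' @return A `pef_helix_axis`: list with `direction` (unit 3-vector),
#'   `centroid`, `fit_rms` (angstrom, RMS spread of the point-to-axis
#'   distances about their mean: 0 for a perfect cylinder) and `n_atoms`.
#' @export
fit_helix_axis <- function(ca_coords) {
  m <- as_coord_matrix(ca_coords)
  n <- nrow(m)
  if (n < 4) abort("helix axis fit needs at least 4 C-alpha positions")
  centroid <- colMeans(m)
  span <- m[n, ] - m[1, ]
  dir <- NULL
  if (n >= 5) {
    # second differences: curvature vectors pointing toward the axis
    s <- m[3:n, , drop = FALSE] - 2 * m[2:(n - 1), , drop = FALSE] +
      m[1:(n - 2), , drop = FALSE]
    mag <- sqrt(rowSums(s^2))
    if (all(mag > 1e-8)) {
      k <- nrow(s)
      cr <- vapply(seq_len(k - 1), function(i) {
        pracma_cross(s[i, ], s[i + 1, ])
      }, numeric(3))
      cr <- t(cr)
      crmag <- sqrt(rowSums(cr^2))
      ok <- crmag > 1e-10
      if (any(ok)) {
        u <- cr[ok, , drop = FALSE] / crmag[ok]
        # align all cross products before averaging
        ref <- u[1, ]
        flip <- (u %*% ref) < 0
        u[flip, ] <- -u[flip, , drop = FALSE]
        dir <- colMeans(u)
        if (sqrt(sum(dir^2)) < 1e-8) dir <- NULL
      }
    }
  }
  if (is.null(dir)) {
    # principal-component fallback (also the collinear 'ideal line' case)
    sv <- svd(sweep(m, 2, centroid))
    dir <- sv$v[, 1]
  }
  dir <- dir / sqrt(sum(dir^2))
  if (sum(dir * span) < 0) dir <- -dir
  # radial spread about the best-fit cylinder: project onto the plane
  # perpendicular to the axis and fit a circle centre (linear Kasa fit)
  basis <- orthonormal_basis(dir)
  q <- sweep(m, 2, centroid) %*% basis
  A <- cbind(2 * q, 1)
  cfit <- if (qr(A)$rank == 3) qr.solve(A, rowSums(q^2)) else c(0, 0, 0)
  r <- sqrt((q[, 1] - cfit[1])^2 + (q[, 2] - cfit[2])^2)
  structure(list(direction = as.numeric(dir),
                 centroid = centroid,
                 fit_rms = sqrt(mean((r - mean(r))^2)),
                 n_atoms = n),
            class = "pef_helix_axis")
}

as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- atom_coords(x)
  m <- as.matrix(x)
  if (ncol(m) != 3) abort("coordinates must be n x 3")
  storage.mode(m) <- "double"
  m
}

#' Angle between two directed helix axes
#'
#' @param a,b `pef_helix_axis` objects or unit 3-vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
interhelix_angle <- function(a, b) {
  va <- if (inherits(a, "pef_helix_axis")) a$direction else a / sqrt(sum(a^2))
  vb <- if (inherits(b, "pef_helix_axis")) b$direction else b / sqrt(sum(b^2))
  d <- max(-1, min(1, sum(va * vb)))
  acos(d) * 180 / pi
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired point sets, by SVD of the covariance matrix with a determinant
#' correction that excludes reflections.
#'
#' @param mobile,target Equal-length n x 3 coordinate matrices (n >= 3,
#'   non-collinear), paired row by row.
#'
#' @return A `pef_superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` (angstrom after transformation) and `n_pairs`.
#'   The transform maps mobile point x to
#'   `rotation %*% (x - mobile centroid) + target centroid + translation`
#'   with `translation = 0`; use [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, target) {
  P <- as_coord_matrix(mobile)
  Q <- as_coord_matrix(target)
  if (nrow(P) != nrow(Q)) {
    abort(sprintf("point sets differ in length (%d vs %d)", nrow(P), nrow(Q)))
  }
  if (nrow(P) < 3) abort("superposition needs at least 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  if (sv$d[2] < 1e-10) abort("degenerate (collinear) geometry: rotation underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q0)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cq),
                 mobile_centroid = as.numeric(cp),
                 rmsd = rmsd, n_pairs = nrow(P)),
            class = "pef_superposition")
}

#' Apply a fitted superposition to coordinates
#'
#' @param coords n x 3 matrix (or data frame with x, y, z).
#' @param sp A `pef_superposition` from [kabsch_superpose()].
#' @return The transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sp) {
  m <- as_coord_matrix(coords)
  sweep(sweep(m, 2, sp$mobile_centroid) %*% t(sp$rotation), 2,
        sp$translation, `+`)
}

#' Per-region RMSD after superposing on a reference region
#'
#' Pairs C-alpha atoms between two structures by (chain, author residue
#' number) intersection, superposes once on `align_chain`/`align_start`/
#' `align_end`, then reports the RMSD of each requested region under that
#' single transform (no per-region re-fitting). This is how sub-domain
#' flexibility is quantified: align on the rigid dimerisation sub-domain
#' (EF4-EF5) and read off how far the EF1-EF3 region has moved.
#'
#' @param mobile,target `pef_structure` objects.
#' @param align_chain Chain used for pairing and alignment.
#' @param align_start,align_end Author residue range to superpose on.
#' @param regions A data frame with columns `region`, `start`, `end`
#'   (author numbering, same chain).
#'
#' @return A tibble: `region`, `n` (paired C-alpha count), `rmsd` (angstrom).
#' @export
region_rmsd <- function(mobile, target, align_chain,
                        align_start = -Inf, align_end = Inf, regions) {
  pairs <- paired_ca(mobile, target, align_chain)
  if (nrow(pairs$mobile) == 0) abort("no common C-alpha residues between structures")
  in_align <- pairs$res_id >= align_start & pairs$res_id <= align_end
  if (sum(in_align) < 3) abort("fewer than 3 paired residues in the alignment range")
  sp <- kabsch_superpose(atom_coords(pairs$mobile)[in_align, , drop = FALSE],
                         atom_coords(pairs$target)[in_align, , drop = FALSE])
  moved <- apply_superposition(atom_coords(pairs$mobile), sp)
  tgt <- atom_coords(pairs$target)
  regions <- as_tibble(regions)
  purrr::pmap_dfr(regions, function(region, start, end, ...) {
    idx <- pairs$res_id >= start & pairs$res_id <= end
    tibble(region = region, n = sum(idx),
           rmsd = if (sum(idx) > 0)
             sqrt(mean(rowSums((moved[idx, , drop = FALSE] -
                                  tgt[idx, , drop = FALSE])^2)))
           else NA_real_)
  })
}

paired_ca <- function(mobile, target, chain) {
  ma <- select_atoms(mobile, chain, atoms = "CA")
  ta <- select_atoms(target, chain, atoms = "CA")
  ma <- ma[!ma$het, ]; ta <- ta[!ta$het, ]
  common <- intersect(ma$res_id, ta$res_id)
  ma <- ma[match(common, ma$res_id), ]
  ta <- ta[match(common, ta$res_id), ]
  list(mobile = ma, target = ta, res_id = common)
}

#' Euclidean distance between two atoms
#'
#' @param a,b Single-row atom records (or numeric 3-vectors).
#' @return Distance in angstrom.
#' @export
atom_distance <- function(a, b) {
  pa <- if (is.data.frame(a)) as.numeric(atom_coords(a)[1, ]) else as.numeric(a)
  pb <- if (is.data.frame(b)) as.numeric(atom_coords(b)[1, ]) else as.numeric(b)
  sqrt(sum((pa - pb)^2))
}

#' Distance-criterion hydrogen bonds between two selections
#'
#' Donor/acceptor candidates are nitrogen and oxygen heavy atoms; a bond is
#' reported for every N/O--N/O pair from distinct residues within the cutoff.
#' No angular term is applied: hydrogens are absent from typical X-ray
#' models at these resolutions, so the criterion is distance-only.
#'
#' @param s A `pef_structure`.
#' @param a_chain,a_start,a_end First selection (donor side).
#' @param b_chain,b_start,b_end Second selection (acceptor side).
#' @param cutoff Heavy-atom distance cutoff in angstrom (default 3.5).
#'
#' @return A tibble sorted by distance: residue/atom identifiers of both
#'   partners and `distance`.
#' @export
find_hbonds <- function(s, a_chain, a_start = -Inf, a_end = Inf,
                        b_chain, b_start = -Inf, b_end = Inf, cutoff = 3.5) {
  if (cutoff <= 0) abort("cutoff must be positive")
  don <- select_atoms(s, a_chain, a_start, a_end)
  acc <- select_atoms(s, b_chain, b_start, b_end)
  don <- don[don$element %in% c("N", "O"), ]
  acc <- acc[acc$element %in% c("N", "O"), ]
  if (nrow(don) == 0 || nrow(acc) == 0) return(empty_hbond_table())
  dmat <- outer_dist(atom_coords(don), atom_coords(acc))
  hits <- which(dmat <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_hbond_table())
  out <- tibble(
    chain_a = don$chain[hits[, 1]], res_id_a = don$res_id[hits[, 1]],
    res_name_a = don$res_name[hits[, 1]], atom_a = don$atom_name[hits[, 1]],
    chain_b = acc$chain[hits[, 2]], res_id_b = acc$res_id[hits[, 2]],
    res_name_b = acc$res_name[hits[, 2]], atom_b = acc$atom_name[hits[, 2]],
    distance = dmat[hits])
  out <- out[!(out$chain_a == out$chain_b & out$res_id_a == out$res_id_b), ]
  arrange(out, .data$distance)
}

empty_hbond_table <- function() {
  tibble(chain_a = character(), res_id_a = integer(), res_name_a = character(),
         atom_a = character(), chain_b = character(), res_id_b = integer(),
         res_name_b = character(), atom_b = character(), distance = double())
}

outer_dist <- function(A, B) {
  # |a - b| for all row pairs without forming n x m x 3 arrays
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; used by the synthetic generators and tests.
#'
#' @param axis 3-vector (normalised internally).
#' @param angle_deg Rotation angle in degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
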