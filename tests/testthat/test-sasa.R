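single_atom <- function(element = "C") {
  new_structure(atom_res("A", 1, 0, res_name = "ALA", atom_name = element,
                         element = element))
}

test_that("a lone atom recovers the analytic sphere area", {
  sa <- compute_sasa(single_atom(), n_points = 960)
  expect_equal(sa$sasa, 4 * pi * 3.1^2, tolerance = 0.005)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  for (d in c(2, 3, 4.5)) {
    s <- new_structure(dplyr::bind_rows(
      atom_res("A", 1, 0, res_name = "ALA", atom_name = "C"),
      atom_res("A", 2, d, res_name = "ALA", atom_name = "C")))
    sa <- compute_sasa(s, n_points = 960)
    R <- 1.7 + 1.4
    cap <- 2 * pi * R * (R - d / 2)         # each sphere loses one cap
    expect_equal(sa$sasa, rep(4 * pi * R^2 - cap, 2), tolerance = 0.02)
  }
})

test_that("a caged atom has zero accessible area", {
  dirs <- rbind(diag(3), -diag(3),
                t(matrix(c(1, 1, 1, 1, 1, -1, 1, -1, 1, -1, 1, 1,
                           1, -1, -1, -1, 1, -1, -1, -1, 1, -1, -1, -1),
                         nrow = 3)) / sqrt(3))
  cage <- purrr::map_dfr(seq_len(nrow(dirs)), function(k) {
    p <- dirs[k, ] * 1.8
    atom_res("A", 1 + k, p[1], p[2], p[3], res_name = "GLY", atom_name = "C")
  })
  s <- new_structure(dplyr::bind_rows(
    atom_res("A", 1, 0, res_name = "ALA", atom_name = "C"), cage))
  sa <- compute_sasa(s, n_points = 960)
  expect_equal(sa$sasa[sa$res_id == 1], 0)
})

test_that("areas are converged at the default point count", {
  # a short strand of 5-atom residues: per-residue areas average the
  # sampling error over several atoms, as in real chains
  res5 <- function(id, x, y) {
    tibble::tibble(chain = "A", res_id = as.integer(id), ins = "",
                   res_name = "LEU",
                   atom_name = c("N", "CA", "C", "O", "CB"),
                   element = c("N", "C", "C", "O", "C"),
                   x = x + c(0, 1.2, 2.4, 3, 1.2), y = y + c(0, 1, 0, 1, 2.4),
                   z = c(0, 0.8, 0, -0.8, 0.4), occ = 1, b = 0, het = FALSE)
  }
  s <- new_structure(purrr::map_dfr(1:8, function(k) res5(k, 3.4 * k,
                                                          2 * (k %% 2))))
  lo <- compute_sasa(s, n_points = 960)
  hi <- compute_sasa(s, n_points = 3840)
  rel <- abs(lo$sasa - hi$sasa) / pmax(hi$sasa, 20)
  expect_lt(max(rel), 0.01)
  expect_lt(abs(sum(lo$sasa) - sum(hi$sasa)) / sum(hi$sasa), 0.005)
})

test_that("per-residue areas agree with an independent reference implementation", {
  # small mixed-element fixture; the oracle is biotite's Shrake-Rupley with
  # the same radii, probe and point count
  withr::with_seed(6, {
    atoms <- purrr::map_dfr(1:4, function(r) {
      purrr::map_dfr(1:3, function(a) {
        atom_res("A", r, rnorm(1, 4 * r, 1.5), rnorm(1, 0, 1.5),
                 rnorm(1, 0, 1.5), res_name = "ALA",
                 atom_name = paste0(c("C", "N", "O")[a], a),
                 element = c("C", "N", "O")[a])
      })
    })
  })
  s <- new_structure(atoms)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, pdb)
  ours <- compute_sasa(s, n_points = 1000)
  py <- sprintf(paste0(
    "import numpy as np\n",
    "import biotite.structure.io.pdb as pdbio\n",
    "import biotite.structure as struc\n",
    "f = pdbio.PDBFile.read('%s')\n",
    "arr = pdbio.get_structure(f, model=1)\n",
    "rad = {'C':1.70,'N':1.55,'O':1.52}\n",
    "radii = np.array([rad[e] for e in arr.element])\n",
    "sasa = struc.sasa(arr, probe_radius=1.4, vdw_radii=radii,",
    " point_number=1000)\n",
    "for rid in sorted(set(arr.res_id)):\n",
    "    print(rid, float(np.sum(sasa[arr.res_id == rid])))\n"), pdb)
  out <- system2("python", c("-"), input = py, stdout = TRUE)
  ref <- read.table(text = out, col.names = c("res_id", "sasa"))
  cmp <- dplyr::inner_join(tibble::as_tibble(ours), ref, by = "res_id")
  expect_equal(nrow(cmp), 4)
  expect_lt(max(abs(cmp$sasa.x - cmp$sasa.y) / pmax(cmp$sasa.y, 1)), 0.02)
})

test_that("exposure-change flagging follows the documented rule", {
  prof <- function(vals) {
    structure(tibble::tibble(chain = "A", res_id = seq_along(vals),
                             res_name = "SER", sasa = vals),
              class = c("pef_sasa", class(tibble::tibble())))
  }
  same <- delta_sasa(prof(c(10, 50, 100)), prof(c(10, 50, 100)))
  expect_false(any(same$flagged))
  up <- delta_sasa(prof(c(10, 50)), prof(c(20, 50)))
  expect_equal(up$relative_change[1], 100)
  expect_true(up$flagged[1]); expect_false(up$flagged[2])
  # the absolute guard suppresses large-percentage/small-area changes
  tiny <- delta_sasa(prof(c(0.5, 50)), prof(c(3, 50)))
  expect_false(tiny$flagged[1])
  # near-antisymmetry under profile swap (denominator guard aside)
  a <- prof(c(20, 40, 80)); b <- prof(c(30, 20, 120))
  fwd <- delta_sasa(a, b); rev <- delta_sasa(b, a)
  expect_true(all(fwd$relative_change * rev$relative_change <= 0))
  pa <- prof(1:3); pb <- prof(1:3); pb$res_id <- 11:13
  expect_error(delta_sasa(pa, pb), "share no residues")
})

test_that("a planted exposure change is recovered with high set overlap", {
  pair <- build_exposure_pair()
  sa <- compute_sasa(pair$apo, n_points = 480)
  sh <- compute_sasa(pair$holo, n_points = 480)
  d <- delta_sasa(sa, sh, threshold = 30)
  flagged <- d$res_id[d$flagged & d$chain == "A"]
  jac <- length(intersect(flagged, pair$targets)) /
    length(union(flagged, pair$targets))
  expect_gte(jac, 0.5)
  expect_setequal(flagged, pair$targets)  # the synthetic case is clean
})

test_that("exposed hydrophobic residues cluster into ranked patches", {
  mk5 <- function(id, x, nm) {
    tibble::tibble(chain = "A", res_id = as.integer(id), ins = "",
                   res_name = nm,
                   atom_name = c("N", "CA", "C", "O", "CB"),
                   element = c("N", "C", "C", "O", "C"),
                   x = x + c(0, 1, 2, 2.5, 1), y = c(0, 0, 0, 1, 2), z = 0,
                   occ = 1, b = 0, het = FALSE)
  }
  s <- new_structure(dplyr::bind_rows(
    mk5(1, 0, "LEU"), mk5(2, 5, "LEU"), mk5(3, 10, "LEU"),
    mk5(10, 60, "SER"), mk5(11, 90, "VAL")))
  sa <- compute_sasa(s, n_points = 480)
  p <- hydrophobic_patches(s, sa, linkage = 6.5)
  expect_equal(nrow(p), 1)          # the lone VAL is dropped as a singleton
  expect_equal(p$n_residues, 3L)
  expect_setequal(p$members[[1]]$res_id, 1:3)
  # patch membership is invariant under atom input order
  withr::with_seed(3, {
    s2 <- new_structure(tibble::as_tibble(s)[sample(nrow(s)), ])
    p2 <- hydrophobic_patches(s2, compute_sasa(s2, n_points = 480))
    expect_setequal(p2$members[[1]]$res_id, p$members[[1]]$res_id)
  })
})

test_that("buried hydrophobic residues form no patches", {
  core <- atom_res("A", 1, 0, res_name = "LEU", atom_name = "CB")
  dirs <- rbind(diag(3), -diag(3),
                t(matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                         nrow = 3)) / sqrt(3))
  shell <- purrr::map_dfr(seq_len(nrow(dirs)), function(k) {
    p <- dirs[k, ] * 2
    atom_res("A", 1 + k, p[1], p[2], p[3], res_name = "SER", atom_name = "OG",
             element = "O")
  })
  s <- new_structure(dplyr::bind_rows(core, shell))
  expect_equal(nrow(hydrophobic_patches(s, compute_sasa(s, n_points = 480))), 0)
})

test_that("interface burial equals the two-run SASA difference and bounds hold", {
  a <- atom_res("A", 1, 0, res_name = "ALA", atom_name = "CB")
  b <- atom_res("B", 1, 4, res_name = "ALA", atom_name = "CB")
  s <- new_structure(dplyr::bind_rows(a, b))
  ib <- interface_burial(s, "A", "B", n_points = 960)
  expect_equal(nrow(ib), 2)
  # oracle: two independent compute_sasa calls
  iso_a <- compute_sasa(new_structure(a), n_points = 960)$sasa
  cplx <- compute_sasa(s, n_points = 960)
  expect_equal(ib$burial[ib$partner == "a"],
               iso_a - cplx$sasa[cplx$chain == "A"], tolerance = 1e-9)
  # additivity: complex SASA <= sum of isolated, difference = total burial
  iso_b <- compute_sasa(new_structure(b), n_points = 960)$sasa
  expect_lte(sum(cplx$sasa), iso_a + iso_b)
  expect_equal(iso_a + iso_b - sum(cplx$sasa), attr(ib, "total_buried"),
               tolerance = 1e-9)
})

test_that("distant partners have an empty interface and bad chain sets error", {
  a <- atom_res("A", 1, 0, res_name = "ALA", atom_name = "CB")
  b <- atom_res("B", 1, 30, res_name = "ALA", atom_name = "CB")
  s <- new_structure(dplyr::bind_rows(a, b))
  expect_equal(nrow(interface_burial(s, "A", "B", n_points = 480)), 0)
  expect_error(interface_burial(s, "A", "A"), "overlap")
  expect_error(interface_burial(s, "A", "C"), "not in structure")
})

test_that("the planted peptide-contact residues are recovered as buried", {
  contacts <- c(97L, 105L, 112L, 164L)
  spectators <- c(30L, 50L, 140L)
  prot <- purrr::map_dfr(sort(c(contacts, spectators)), function(id) {
    atom_res("A", id, 25 * match(id, sort(c(contacts, spectators))),
             res_name = "LEU", atom_name = "CB")
  })
  pep <- purrr::map_dfr(seq_along(contacts), function(k) {
    atom_res("P", 12L + k,
             25 * match(contacts[k], sort(c(contacts, spectators))) + 4,
             res_name = "TYR", atom_name = "CB")
  })
  s <- new_structure(dplyr::bind_rows(prot, pep))
  ib <- interface_burial(s, "A", "P", n_points = 480)
  expect_setequal(ib$res_id[ib$partner == "a"], contacts)
})
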