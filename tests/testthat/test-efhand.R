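test_that("auto assignment finds an ideal helix embedded in coil", {
  helix <- build_helix(12, origin = c(0, 0, 0), res_start = 11L)
  # extended flanks: 3.8-angstrom spacing on a straight line is non-helical
  coil_n <- atom_res("A", 1, 0)[0, ]
  mk_coil <- function(ids, ori, dir) {
    purrr::map_dfr(seq_along(ids), function(k) {
      p <- ori + (k - 1) * 3.8 * dir
      atom_res("A", ids[k], p[1], p[2], p[3], res_name = "ALA",
               atom_name = "CA")
    })
  }
  s <- new_structure(dplyr::bind_rows(
    mk_coil(1:10, c(0, 30, 0), c(1, 0, 0)),
    tibble::as_tibble(helix),
    mk_coil(23:32, c(0, -30, 0), c(0, 1, 0))))
  segs <- assign_helices(s, "A", method = "auto", label = "none")
  expect_equal(nrow(segs), 1)
  expect_lte(abs(segs$start - 11), 1)
  expect_lte(abs(segs$end - 22), 1)
})

test_that("auto assignment errors on an all-coil chain", {
  coil <- purrr::map_dfr(1:30, function(k) {
    atom_res("A", k, 3.8 * k, 0, 0, res_name = "ALA", atom_name = "CA")
  })
  expect_error(assign_helices(new_structure(coil), "A", method = "auto",
                              label = "none"), "no helical")
  # a single helix cannot be labelled A-H
  expect_error(assign_helices(build_helix(12), "A", method = "auto"),
               "registry")
})

test_that("auto assignment labels the eight PEF helices in sequence order", {
  m <- build_pef_monomer(sorcin_holo_angles, seed = 21)
  ann <- assign_helices(m$structure, "A", method = "auto")
  expect_equal(ann$helix, LETTERS[1:8])
  expect_equal(ann$start, m$annotations$start)
  expect_equal(ann$end, m$annotations$end)
})

test_that("registry and file modes supply annotations", {
  reg <- pef_registry("sorcin")
  expect_equal(nrow(reg), 8)
  expect_true(reg$start[reg$helix == "A"] > 32)  # after the N-terminal domain
  expect_true(all(reg$start <= reg$end))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(reg, path)
  s <- build_pef_monomer(sorcin_apo_angles, seed = 2)$structure
  ann <- assign_helices(s, "A", method = "file", file = path)
  expect_equal(ann, reg)
})

test_that("prescribed EF-hand opening angles are recovered within 0.5 degrees", {
  for (theta in c(10, 35, 50, 90, 120, 170)) {
    pair <- build_efhand_pair(theta, theta)
    rep <- efhand_angles(pair$apo, "A", pair$annotations, pair$ef_defs)
    expect_equal(rep$theta[rep$angle == "EF1"], theta, tolerance = 0.5 / theta)
  }
})

test_that("full synthetic monomers reproduce their planted angle sets", {
  for (seed in c(1, 17, 23)) {
    rep <- measure_monomer(sorcin_apo_angles, seed = seed)
    expect_equal(rep$theta, unname(sorcin_apo_angles[rep$angle]),
                 tolerance = 0.02)
  }
})

test_that("opening angles are invariant under rigid motion of the structure", {
  m <- build_pef_monomer(sorcin_holo_angles, seed = 5)
  base <- efhand_angles(m$structure, "A", m$annotations)$theta
  withr::with_seed(8, {
    for (i in 1:5) {
      tr <- random_rigid()
      got <- efhand_angles(transform_structure(m$structure, tr$R, tr$t),
                           "A", m$annotations)$theta
      expect_equal(got, base, tolerance = 1e-6)
    }
  })
})

test_that("angles are robust to +/- 2 residue boundary shifts on ideal helices", {
  m <- build_pef_monomer(sorcin_apo_angles, seed = 9, n_residues = 14)
  base <- efhand_angles(m$structure, "A", m$annotations)$theta
  for (shift in c(-2L, 2L)) {
    ann <- m$annotations
    ann$start <- ann$start + max(shift, 0)
    ann$end <- ann$end + min(shift, 0)
    got <- efhand_angles(m$structure, "A", ann)$theta
    expect_true(all(abs(got - base) < 5))
  }
})

test_that("delta tables are exact signed differences and antisymmetric", {
  a <- measure_monomer(sorcin_apo_angles, seed = 1, label = "apo")
  b <- measure_monomer(sorcin_holo_angles, seed = 2, label = "holo")
  self <- delta_table(a, a)
  expect_true(all(self$delta == 0))
  fwd <- delta_table(a, b)
  rev <- delta_table(b, a)
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$delta, fwd$theta_holo - fwd$theta_apo)
  bad <- a[a$angle != "EF1", ]
  expect_error(delta_table(a, bad), "different angle sets")
})

test_that("the apo-to-holo deltas match the planted calcium response", {
  # Sorcin-like pair: EF1 and EF3 open widely, hD-hG tilts by ~21 degrees
  d <- delta_table(measure_monomer(sorcin_apo_angles, 1, "apo"),
                   measure_monomer(sorcin_holo_angles, 2, "holo"))
  expect_equal(d$delta[d$angle == "EF1"], 18.4, tolerance = 0.5 / 18.4)
  expect_equal(d$delta[d$angle == "EF3"], 14.5, tolerance = 0.5 / 14.5)
  expect_equal(d$delta[d$angle == "hD-hG"], 20.6, tolerance = 0.5 / 20.6)
  # calpain-dVI-like pair: similar EF1/EF3 opening, small hD-hG change
  d2 <- delta_table(measure_monomer(calpain_apo_angles, 3, "apo"),
                    measure_monomer(calpain_holo_angles, 4, "holo"))
  expect_equal(d2$delta[d2$angle == "EF1"], 20.7, tolerance = 0.5 / 20.7)
  expect_equal(d2$delta[d2$angle == "hD-hG"], 5.3, tolerance = 0.5 / 5.3)
})

test_that("family comparison assembles per-entry rows and pair deltas", {
  mk <- function(angles, seed, label) {
    m <- build_pef_monomer(angles, seed = seed)
    list(label = label, structure = m$structure, chain = "A",
         annotations = m$annotations)
  }
  one <- compare_family(list(mk(sorcin_apo_angles, 1, "apoSor")))
  expect_equal(nrow(one$angles), 1)
  expect_null(one$deltas)
  fam <- compare_family(
    list(mk(sorcin_apo_angles, 1, "apoSor"),
         mk(sorcin_holo_angles, 2, "CaSor"),
         mk(pdcd6_apo_angles, 3, "PDCD6-apo"),
         mk(pdcd6_holo_angles, 4, "PDCD6-Ca")),
    pairs = tibble::tibble(apo = c("apoSor", "PDCD6-apo"),
                           holo = c("CaSor", "PDCD6-Ca")))
  expect_equal(nrow(fam$angles), 4)
  expect_equal(fam$angles$`hD-hG`,
               unname(c(sorcin_apo_angles["hD-hG"], sorcin_holo_angles["hD-hG"],
                        pdcd6_apo_angles["hD-hG"], pdcd6_holo_angles["hD-hG"])),
               tolerance = 0.01)
  sor <- fam$deltas[fam$deltas$apo == "apoSor" & fam$deltas$angle == "hD-hG", ]
  expect_equal(sor$delta, 20.6, tolerance = 0.02)
  expect_error(compare_family(list(mk(sorcin_apo_angles, 1, "x"),
                                   mk(sorcin_holo_angles, 2, "x"))),
               "duplicate")
})
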