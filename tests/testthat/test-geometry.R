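test_that("helix-axis recovery is exact on ideal helices", {
  h <- build_helix(12)
  ax <- fit_helix_axis(h)
  expect_lt(max(abs(ax$direction - c(0, 0, 1))), 1e-6)
  expect_lt(ax$fit_rms, 1e-9)
  expect_equal(ax$n_atoms, 12)
  # rotation by 30 degrees about x is recovered to better than 0.01 degrees
  h30 <- transform_structure(h, rotation_matrix(c(1, 0, 0), 30), c(0, 0, 0))
  expect_equal(interhelix_angle(fit_helix_axis(h30)$direction, c(0, 0, 1)),
               30, tolerance = 0.01 / 30)
})

test_that("helix-axis direction co-rotates exactly under rigid motion", {
  h <- build_helix(15, twist = 99, rise = 1.48)
  d0 <- fit_helix_axis(h)$direction
  withr::with_seed(42, {
    for (i in 1:10) {
      tr <- random_rigid()
      d1 <- fit_helix_axis(transform_structure(h, tr$R, tr$t))$direction
      expect_lt(interhelix_angle(d1, as.numeric(tr$R %*% d0)), 1e-4)
    }
  })
})

test_that("axis fit rejects short input and degrades gracefully to a line", {
  expect_error(fit_helix_axis(matrix(rnorm(9), 3)), "at least 4")
  line <- cbind(0, 0, seq(0, 10, length.out = 8))
  expect_lt(interhelix_angle(fit_helix_axis(line)$direction, c(0, 0, 1)), 1e-6)
})

test_that("interhelix angles follow the directed-axis conventions", {
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(interhelix_angle(c(0, 0, 1), c(0, 0, -1)), 180)
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- rnorm(3); b <- rnorm(3)
      expect_equal(interhelix_angle(a, b) + interhelix_angle(a, -b), 180,
                   tolerance = 1e-9)
    }
  })
})

test_that("Kabsch superposition solves identity and known-transform cases", {
  withr::with_seed(1, {
    pts <- matrix(rnorm(30, sd = 5), ncol = 3)
    self <- kabsch_superpose(pts, pts)
    expect_equal(self$rmsd, 0, tolerance = 1e-9)
    expect_equal(self$rotation, diag(3), tolerance = 1e-9)
    for (i in 1:5) {
      tr <- random_rigid()
      moved <- sweep(pts %*% t(tr$R), 2, tr$t, `+`)
      sp <- kabsch_superpose(pts, moved)
      expect_lt(sp$rmsd, 1e-9)
      expect_lt(max(abs(sp$rotation - tr$R)), 1e-6)
      expect_lt(max(abs(apply_superposition(pts, sp) - moved)), 1e-9)
    }
  })
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)), "length")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("superposition rmsd is invariant under rigid pre-motion of either set", {
  withr::with_seed(2, {
    a <- matrix(rnorm(45, sd = 4), ncol = 3)
    b <- a + matrix(rnorm(45, sd = 0.6), ncol = 3)
    base <- kabsch_superpose(a, b)$rmsd
    for (i in 1:5) {
      tr <- random_rigid()
      a2 <- sweep(a %*% t(tr$R), 2, tr$t, `+`)
      expect_equal(kabsch_superpose(a2, b)$rmsd, base, tolerance = 1e-9)
      expect_equal(kabsch_superpose(a, sweep(b %*% t(tr$R), 2, tr$t, `+`))$rmsd,
                   base, tolerance = 1e-9)
    }
  })
})

test_that("Kabsch rmsd matches a dense rotation-grid oracle", {
  withr::with_seed(3, {
    a <- matrix(rnorm(12, sd = 3), ncol = 3)
    b <- a + matrix(rnorm(12, sd = 0.5), ncol = 3)
    fit <- kabsch_superpose(a, b)$rmsd
    a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
    grid <- seq(0, 345, by = 15) * pi / 180
    best <- Inf
    for (al in grid) for (be in seq(0, pi, by = 15 * pi / 180)) for (ga in grid) {
      Rz1 <- rotation_matrix(c(0, 0, 1), al * 180 / pi)
      Ry <- rotation_matrix(c(0, 1, 0), be * 180 / pi)
      Rz2 <- rotation_matrix(c(0, 0, 1), ga * 180 / pi)
      R <- Rz1 %*% Ry %*% Rz2
      best <- min(best, sqrt(mean(rowSums((a0 %*% t(R) - b0)^2))))
    }
    expect_lte(fit, best + 1e-12)   # optimal beats every grid rotation
    expect_lt(best - fit, 0.35)     # and the grid comes close at 15-degree steps
  })
})

test_that("atom distances follow the Euclidean definition", {
  expect_equal(atom_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  s <- build_peptide_interface_fixture()
  oh <- s[s$chain == "P" & s$res_id == 13 & s$atom_name == "OH", ]
  oe2 <- s[s$chain == "A" & s$res_id == 97 & s$atom_name == "OE2", ]
  expect_equal(atom_distance(oh, oe2), 2.78, tolerance = 1e-9)
})

test_that("hydrogen-bond detection applies the distance criterion to N/O pairs", {
  far <- new_structure(dplyr::bind_rows(
    atom_res("A", 1, 0, element = "O", atom_name = "O", res_name = "SER"),
    atom_res("B", 1, 5, element = "O", atom_name = "O", res_name = "SER")))
  expect_equal(nrow(find_hbonds(far, "A", b_chain = "B")), 0)
  near <- new_structure(dplyr::bind_rows(
    atom_res("A", 1, 0, element = "O", atom_name = "OG", res_name = "SER"),
    atom_res("A", 1, 1, element = "C", atom_name = "CB", res_name = "SER"),
    atom_res("B", 1, 2.8, element = "O", atom_name = "O", res_name = "GLY")))
  hb <- find_hbonds(near, "A", b_chain = "B")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8)
  # planted peptide-interface distances are recovered exactly
  s <- build_peptide_interface_fixture()
  hb2 <- find_hbonds(s, "P", b_chain = "A", cutoff = 3.5)
  expect_setequal(round(hb2$distance, 2), c(2.78, 2.90))
})

test_that("region rmsd isolates the moved sub-domain under one alignment", {
  m <- build_pef_monomer(sorcin_apo_angles, seed = 13)
  s <- m$structure
  moved <- s
  idx <- moved$res_id <= 72          # helices A-D: the mobile half
  xyz <- atom_coords(moved)
  xyz[idx, ] <- xyz[idx, ] %*% t(rotation_matrix(c(0, 1, 0), 20))
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  regions <- tibble::tibble(region = c("EF1-3-half", "EF4-5-half"),
                            start = c(1, 101), end = c(72, 160))
  rr <- region_rmsd(moved, s, "A", align_start = 101, align_end = 160,
                    regions = regions)
  expect_equal(rr$rmsd[rr$region == "EF4-5-half"], 0, tolerance = 1e-9)
  # oracle: direct coordinate displacement of the rotated block
  direct <- sqrt(mean(rowSums((xyz[idx, ] - atom_coords(s)[idx, ])^2)))
  expect_equal(rr$rmsd[rr$region == "EF1-3-half"], direct, tolerance = 1e-9)
  ident <- region_rmsd(s, s, "A", regions = regions)
  expect_true(all(ident$rmsd < 1e-9))
})
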