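test_that("plane fitting is exact on coplanar points and matches analytics", {
  pts <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  pl <- fit_plane(pts)
  expect_equal(pl$rmsd, 0, tolerance = 1e-12)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  # plane z = x has normal (1, 0, -1) / sqrt(2)
  pts2 <- cbind(c(0, 1, 2, 0.5), c(0, 1, -1, 2), c(0, 1, 2, 0.5))
  pl2 <- fit_plane(pts2)
  expect_equal(abs(pl2$normal), c(1, 0, 1) / sqrt(2), tolerance = 1e-9)
  expect_error(fit_plane(cbind(0:3, 0:3, 0:3)), "collinear")
})

test_that("plane normal is recovered within 2 degrees under 0.05 A noise", {
  true_n <- c(0, 0, 1)
  worst <- 0
  for (seed in 1:100) {
    set.seed(seed)
    pts <- cbind(runif(24, -3, 3), runif(24, -3, 3), rnorm(24, 0, 0.05))
    n <- fit_plane(pts)$normal
    ang <- acos(min(1, abs(sum(n * true_n)))) * 180 / pi
    worst <- max(worst, ang)
  }
  expect_lt(worst, 2)
})

test_that("extraction finds the corrin by chemistry and names all equatorial nitrogens", {
  cor <- extract_corrin(make_corrin(10))
  expect_setequal(cor$equatorial_n$name, c("N21", "N22", "N23", "N24"))
  expect_equal(cor$co$element, "Co")
  expect_equal(cor$dmb_n$name, "N3B")
  expect_null(cor$beta_atom)  # nothing within 3 A above the ring
  # zero candidates is an error
  shell <- make_ca_trace(10)
  expect_error(extract_corrin(shell), "corrin candidate")
})

test_that("beta-axial atom is the glutathione sulfur or the histidine NE2", {
  g <- extract_corrin(make_tc_complex("GSCbl"))
  expect_equal(g$beta_atom$name, "SG2")
  expect_equal(g$beta_atom$resname, "GSH")
  h <- extract_corrin(make_tc_complex("HOCbl"))
  expect_equal(h$beta_atom$name, "NE2")
  expect_equal(h$beta_atom$resseq, 193L)
})

test_that("fold angle is exact on constructions and matches the plane-fit oracle", {
  expect_equal(corrin_fold_angle(make_corrin(0)), 0, tolerance = 1e-6)
  s <- make_corrin(10)
  got <- corrin_fold_angle(s)
  expect_equal(got, 10, tolerance = 1e-6)
  # independent oracle: optimisation-based plane fit on the same atoms
  atoms <- as.data.frame(s)
  xyz_of <- function(nms) as.matrix(atoms[match(nms, atoms$name),
                                          c("x", "y", "z")])
  ora <- oracle_plane_angle(
    xyz_of(c("N21", "C4", "C5", "C6", "N22", "C9", "C10")),
    xyz_of(c("C10", "C11", "N23", "C14", "C15", "C16", "N24")))
  expect_equal(got, ora, tolerance = 1e-4)
})

test_that("fold angle is invariant under rigid motion and monotone in the generator", {
  s <- make_corrin(7.3)
  base <- corrin_fold_angle(s)
  for (seed in 1:5) {
    moved <- move_rigid(as.data.frame(s), random_rigid_transform(seed))
    moved <- b12_structure(moved)
    expect_equal(corrin_fold_angle(moved), base, tolerance = 1e-9)
  }
  angles <- vapply(c(0, 2, 5, 10, 20),
                   function(th) corrin_fold_angle(make_corrin(th)), numeric(1))
  expect_true(all(diff(angles) > 0))
  expect_true(all(abs(angles - c(0, 2, 5, 10, 20)) < 0.5))
})

test_that("missing butterfly atoms are reported by name", {
  s <- as.data.frame(make_corrin(5))
  s <- s[s$name != "C14", ]
  expect_error(corrin_fold_angle(b12_structure(s)), "C14")
})

test_that("axial geometry reports constructed distances and base-on state", {
  g <- axial_geometry(make_tc_complex("GSCbl"))
  expect_equal(g$co_alpha_dist, 2.2, tolerance = 1e-6)
  expect_equal(g$co_beta_dist, 2.4, tolerance = 1e-6)
  expect_match(g$beta_ligand_identity, "GSH")
  expect_true(g$base_on)
  h <- axial_geometry(make_tc_complex("HOCbl"))
  expect_equal(h$co_beta_dist, 2.1, tolerance = 1e-6)
  expect_match(h$beta_ligand_identity, "HIS 193 NE2")
  # bare corrin: no beta ligand
  b <- axial_geometry(make_corrin(5))
  expect_true(is.na(b$co_beta_dist))
  expect_equal(b$beta_ligand_identity, "none")
})
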