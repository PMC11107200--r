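.mini <- function(df) b12_structure(df)

.pair_structure <- function(d, lig_el = "N", pro_el = "O") {
  .mini(data.frame(
    name = c(lig_el, pro_el), resname = c("GSH", "SER"),
    chain = c("L", "A"), resseq = c(1, 10),
    x = c(0, d), y = 0, z = 0, element = c(lig_el, pro_el)))
}

test_that("direct polar contacts follow the distance cutoff", {
  ct <- polar_contacts(.pair_structure(2.8), ligand = "chain L")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$kind, "direct")
  expect_equal(ct$distance, 2.8, tolerance = 1e-9)
  expect_equal(nrow(polar_contacts(.pair_structure(4.0), ligand = "chain L")),
               0)
  # apolar atoms never count
  cc <- .pair_structure(2.8, lig_el = "C")
  expect_equal(nrow(polar_contacts(cc, ligand = "chain L")), 0)
})

test_that("water bridges require both legs within the cutoff", {
  s <- .mini(data.frame(
    name = c("N1", "O", "OG"), resname = c("GSH", "HOH", "SER"),
    chain = c("L", "W", "A"), resseq = c(1, 300, 10),
    x = c(0, 2.8, 5.6), y = 0, z = 0, element = c("N", "O", "O")))
  ct <- polar_contacts(s, ligand = "chain L")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$kind, "water_bridge")
  expect_match(ct$water, "HOH")
  # pull the protein atom out of range of the water: no bridge
  s2 <- s; s2$x[3] <- 7.0
  expect_equal(nrow(polar_contacts(b12_structure(as.data.frame(s2)),
                                   ligand = "chain L")), 0)
})

test_that("the designed glutathione pocket shows 14 contacts, mostly water-mediated", {
  s <- make_tc_complex("GSCbl")
  ct <- polar_contacts(s, ligand = "resn GSH")
  expect_equal(nrow(ct), 14)
  expect_equal(attr(ct, "n_direct"), 4)
  expect_equal(attr(ct, "n_water"), 10)
  expect_gt(attr(ct, "n_water"), attr(ct, "n_direct"))
  # direct partners are the designed serine/threonine/tyrosine atoms
  expect_setequal(
    ct$protein_atom[ct$kind == "direct"],
    c("A/SER195/OG", "A/THR198/OG1", "A/TYR154/N", "A/TYR155/N"))
})

test_that("contact counts are invariant under rigid motion", {
  s <- make_tc_complex("GSCbl")
  base <- nrow(polar_contacts(s, ligand = "resn GSH"))
  moved <- b12_structure(move_rigid(as.data.frame(s),
                                    random_rigid_transform(13)))
  expect_equal(nrow(polar_contacts(moved, ligand = "resn GSH")), base)
})

test_that("disulfide detection pairs SG atoms greedily and uniquely", {
  two <- .mini(data.frame(
    name = "SG", resname = "CYS", chain = "A", resseq = c(5, 40),
    x = c(0, 2.05), y = 0, z = 0, element = "S"))
  got <- find_disulfides(two)
  expect_equal(nrow(got), 1)
  expect_equal(got$distance, 2.05, tolerance = 1e-9)
  far <- two; far$x[2] <- 3.5
  expect_equal(nrow(find_disulfides(b12_structure(as.data.frame(far)))), 0)
  # three in a row: only the closest pair forms, no cysteine reused
  three <- .mini(data.frame(
    name = "SG", resname = "CYS", chain = "A", resseq = c(1, 2, 3),
    x = c(0, 2.0, 4.1), y = 0, z = 0, element = "S"))
  got3 <- find_disulfides(three)
  expect_equal(nrow(got3), 1)
  expect_equal(got3$resno1, 1)
  expect_equal(got3$resno2, 2)
})

test_that("the synthetic transporter contains the four canonical disulfides", {
  ss <- find_disulfides(make_tc_complex("HOCbl"))
  expect_equal(nrow(ss), 4)
  expect_equal(ss[, c("resno1", "resno2")],
               data.frame(resno1 = c(21L, 83L, 116L, 165L),
                          resno2 = c(268L, 96L, 310L, 208L)),
               ignore_attr = TRUE)
})

test_that("helix-dipole contact tests the first two helix residues", {
  s <- make_tc_complex("GSCbl")
  h <- helix_dipole_contact(s, "resn GSH and name O11,O12", c(154, 155))
  expect_true(h$contact)
  expect_lte(h$min_dist, 3.5)
  # a helix elsewhere is out of reach
  h2 <- helix_dipole_contact(s, "resn GSH and name O11,O12", c(21, 268))
  expect_false(h2$contact)
  expect_error(helix_dipole_contact(s, "resn GSH and name SG2", c(154, 155)),
               "no oxygens")
})
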