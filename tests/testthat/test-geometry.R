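# Dihedrals/Ramachandran classification, radius of gyration, RMSD.

test_that("ideal helix and strand land in the core region", {
  helix <- build_fixture("helix")$structure
  dh <- backbone_dihedrals(helix)
  interior <- dh[!(dh$region == "incomplete"), ]
  expect_equal(unique(interior$region), "core")
  expect_equal(interior$phi, rep(-57, nrow(interior)), tolerance = 1e-6)
  expect_equal(interior$psi, rep(-47, nrow(interior)), tolerance = 1e-6)
  # terminals lack one dihedral each
  expect_equal(sum(dh$region == "incomplete"), 2L)

  strand <- build_fixture("strand")$structure
  ds <- backbone_dihedrals(strand)
  expect_equal(unique(ds$region[ds$region != "incomplete"]), "core")
})

test_that("allowed margin and outliers classify as documented", {
  # phi just outside the core rectangle but within the 20 degree margin
  pep <- build_fixture(fixture_spec("extended_peptide",
                                    list(sequence = "GGGGG",
                                         phi = -15, psi = 150)))$structure
  d <- backbone_dihedrals(pep)
  expect_true(all(d$region[d$region != "incomplete"] == "allowed"))

  out <- build_fixture(fixture_spec("extended_peptide",
                                    list(sequence = "GGGGG",
                                         phi = 120, psi = -120)))$structure
  do_ <- backbone_dihedrals(out)
  expect_true(all(do_$region[do_$region != "incomplete"] == "outlier"))
})

test_that("degenerate collinear backbones are incomplete with a warning", {
  rows <- list()
  for (i in 1:3) {
    base <- (i - 1) * 4
    rows <- c(rows, list(
      toy_atom("N", c(base, 0, 0), "GLY", "A", i, record = "ATOM"),
      toy_atom("CA", c(base + 1.4, 0, 0), "GLY", "A", i, record = "ATOM"),
      toy_atom("C", c(base + 2.9, 0, 0), "GLY", "A", i, record = "ATOM")))
  }
  st <- toy_structure(rows)
  expect_warning(d <- backbone_dihedrals(st), "collinear|degenerate")
  expect_true(all(d$region == "incomplete"))
})

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  single <- carbon_cloud(matrix(c(0, 0, 0), 1))
  expect_equal(radius_of_gyration(single), 0)

  pair <- carbon_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(pair), 1.0)

  cube <- carbon_cloud(as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2))))
  expect_equal(radius_of_gyration(cube), sqrt(3))
  expect_equal(radius_of_gyration(transform_structure(cube)), sqrt(3))
})

test_that("rmsd obeys identity, rotation invariance, and closed forms", {
  fx <- build_fixture("exposed_tyr")$structure
  expect_equal(rmsd(fx, fx), 0)
  rot <- transform_structure(fx)
  expect_lt(rmsd(fx, rot, superpose = TRUE), 1e-6)
  expect_gt(rmsd(fx, rot, superpose = FALSE), 1)

  a <- carbon_cloud(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  b_atoms <- a$atoms
  b_atoms$y[2] <- 1  # displace one atom by 1 A
  b <- pdb_structure(b_atoms[setdiff(names(b_atoms), "hydrogen")])
  expect_equal(rmsd(a, b, superpose = FALSE), sqrt(1 / 3))
})

test_that("rmsd is symmetric, triangle-bounded, and checks atom sets", {
  a <- carbon_cloud(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  perturb <- function(st, dz) {
    atoms <- st$atoms
    atoms$z <- atoms$z + dz * seq_len(nrow(atoms))
    pdb_structure(atoms[setdiff(names(atoms), "hydrogen")])
  }
  b <- perturb(a, 0.3)
  c_ <- perturb(a, -0.2)
  for (sup in c(TRUE, FALSE)) {
    expect_equal(rmsd(a, b, sup), rmsd(b, a, sup), tolerance = 1e-6)
    expect_lte(rmsd(a, c_, sup),
               rmsd(a, b, sup) + rmsd(b, c_, sup) + 1e-6)
  }
  bad <- carbon_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(rmsd(a, bad), "mismatch")
})
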