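# Shrake-Rupley engine against closed forms and the Monte-Carlo oracle.

iso_area <- 4 * pi * (1.7 + 1.4)^2  # isolated carbon, probe 1.4

test_that("sphere_points are unit vectors, near-uniform, and validated", {
  p <- sphere_points(960)
  expect_equal(dim(p), c(960L, 3L))
  expect_lt(max(abs(sqrt(rowSums(p^2)) - 1)), 1e-12)
  expect_lt(sqrt(sum(colMeans(sphere_points(100))^2)), 0.05)
  expect_error(sphere_points(4), ">= 12")
  expect_identical(sphere_points(100), sphere_points(100))
})

test_that("isolated atom matches the closed-form sphere area", {
  fx <- build_fixture("isolated_atom")
  res <- compute_sasa(fx$structure)
  expect_equal(unname(res$per_atom), iso_area, tolerance = 0.005)
  expect_equal(unname(res$per_residue), unname(res$per_atom))
})

test_that("two equal intersecting spheres match the spherical-cap formula", {
  d <- 3.1
  fx <- build_fixture(fixture_spec("atom_pair", list(distance = d)))
  res <- compute_sasa(fx$structure)
  r <- 3.1
  expected <- 4 * pi * r^2 - 2 * pi * r * (r - d / 2)
  expect_equal(unname(res$per_atom[1]), expected, tolerance = 0.01)
  expect_equal(unname(res$per_atom[2]), expected, tolerance = 0.01)
})

test_that("a lattice-enclosed atom is fully buried", {
  fx <- build_fixture("buried_atom")
  res <- compute_sasa(fx$structure)
  expect_equal(unname(res$per_atom[1]), 0)
  mc <- mc_sasa_oracle(fx$structure, n_samples = 2000, seed = 7)
  expect_equal(unname(mc$per_atom[1]), 0)
})

test_that("per-residue areas are exact sums of atom areas", {
  fx <- build_fixture("exposed_tyr")
  res <- compute_sasa(fx$structure)
  keys <- residue_keys(fx$structure)[!fx$structure$atoms$hydrogen]
  for (k in names(res$per_residue)) {
    expect_equal(unname(res$per_residue[k]),
                 sum(res$per_atom[keys == k]))
  }
  expect_true(all(res$per_atom >= 0))
})

test_that("relative accessibility divides by the reference maximum", {
  fx <- build_fixture("exposed_tyr")
  res <- compute_sasa(fx$structure)
  tyr_area <- unname(res$per_residue["A:2: "])
  ref <- c(GLY = 1e6, TYR = tyr_area * 2)  # force relative = 0.5
  rel <- relative_sasa(res, ref)
  expect_equal(unname(rel$relative_per_residue["A:2: "]), 0.5)
  expect_error(relative_sasa(res, c(GLY = 104)), "TYR")
})

test_that("an extended host leaves the central tyrosine near-maximally exposed", {
  fx <- build_fixture("exposed_tyr")
  rel <- relative_sasa(compute_sasa(fx$structure))
  expect_gte(unname(rel$relative_per_residue["A:2: "]), 0.85)
})

test_that("deterministic areas agree with the Monte-Carlo oracle within 3 SE", {
  fx <- build_fixture("isolated_atom")
  mc <- mc_sasa_oracle(fx$structure, n_samples = 1e5, seed = 1)
  expect_lt(abs(unname(mc$per_atom[1]) - iso_area),
            3 * max(unname(mc$se[1]), 1e-9) + 1e-9)

  for (kind in c("atom_pair", "exposed_tyr")) {
    fx <- build_fixture(kind)
    det <- compute_sasa(fx$structure)
    mc <- mc_sasa_oracle(fx$structure, n_samples = 2e4, seed = 42)
    # allow a small determinism term for the finite spiral grid
    tol <- 3 * mc$se + 0.015 * 4 * pi * 3.1^2
    expect_true(all(abs(det$per_atom - mc$per_atom) <= tol))
  }
  expect_error(mc_sasa_oracle(fx$structure, n_samples = 10), ">= 1000")
})

test_that("areas are invariant under rigid motion (<= 1% drift)", {
  fx <- build_fixture("exposed_tyr")
  base <- compute_sasa(fx$structure)
  moved <- compute_sasa(transform_structure(fx$structure))
  drift <- abs(sum(moved$per_atom) - sum(base$per_atom)) /
    sum(base$per_atom)
  expect_lt(drift, 0.01)
  # per-residue drift is grid-resolution limited at 960 points
  per_res_drift <- abs(moved$per_residue - base$per_residue) /
    pmax(base$per_residue, 1)
  expect_lt(max(per_res_drift), 0.02)
})

test_that("locality: a far-away atom changes nothing", {
  fx <- build_fixture("atom_pair")
  base <- compute_sasa(fx$structure)
  far <- toy_atom("C", c(50, 50, 50), resseq = 99L)
  atoms <- rbind(fx$structure$atoms[setdiff(names(fx$structure$atoms),
                                            "hydrogen")], far)
  atoms$serial <- seq_len(nrow(atoms))
  bigger <- compute_sasa(pdb_structure(atoms))
  expect_equal(unname(bigger$per_atom[1:2]), unname(base$per_atom[1:2]))
})

test_that("monotonicity: adding a neighbor never increases any area", {
  base_coords <- rbind(c(0, 0, 0), c(3.1, 0, 0))
  st <- carbon_cloud(base_coords)
  base <- compute_sasa(st)
  for (extra in list(c(1.5, 2.5, 0), c(0, -3, 0), c(2, 2, 2))) {
    st2 <- carbon_cloud(rbind(base_coords, extra))
    grown <- compute_sasa(st2)
    expect_true(all(grown$per_atom[1:2] <= base$per_atom[1:2] + 1e-9))
  }
})

test_that("point-count convergence is within 2%", {
  fx <- build_fixture("exposed_tyr")
  a960 <- compute_sasa(fx$structure, sasa_params(n_sphere_points = 960))
  a4000 <- compute_sasa(fx$structure, sasa_params(n_sphere_points = 4000))
  rel_diff <- abs(sum(a960$per_atom) - sum(a4000$per_atom)) /
    sum(a4000$per_atom)
  expect_lt(rel_diff, 0.02)
})

test_that("unknown elements and hydrogen handling are explicit", {
  rows <- list(toy_atom("XX", c(0, 0, 0), element = "XX"))
  st <- toy_structure(rows)
  expect_error(compute_sasa(st), "XX")

  rows <- list(toy_atom("C", c(0, 0, 0)),
               toy_atom("H", c(1.1, 0, 0), resseq = 2L, element = "H"))
  st <- toy_structure(rows)
  heavy_only <- compute_sasa(st)
  expect_length(heavy_only$per_atom, 1L)
  expect_equal(unname(heavy_only$per_atom[1]), iso_area, tolerance = 0.005)
  with_h <- compute_sasa(st, sasa_params(include_hydrogens = TRUE))
  expect_length(with_h$per_atom, 2L)
  expect_lt(unname(with_h$per_atom[1]), iso_area)
})
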