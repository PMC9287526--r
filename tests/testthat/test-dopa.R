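# Tyrosine classification and in-structure DOPA conversion.

test_that("whole-residue threshold is strict ('more than 55%')", {
  fx <- build_fixture("exposed_tyr")
  sasa <- relative_sasa(compute_sasa(fx$structure))
  rel <- unname(sasa$relative_per_residue["A:2: "])
  at_threshold <- classify_tyrosines(
    fx$structure, sasa, accessibility_params(threshold = rel))
  expect_false(at_threshold$per_tyrosine$modifiable[1])
  below <- classify_tyrosines(
    fx$structure, sasa, accessibility_params(threshold = rel - 1e-6))
  expect_true(below$per_tyrosine$modifiable[1])
})

test_that("exposed and buried fixtures classify consistently in both modes", {
  fx_exp <- build_fixture("exposed_tyr")
  fx_bur <- build_fixture("buried_tyr")
  sasa_exp <- relative_sasa(compute_sasa(fx_exp$structure))
  sasa_bur <- relative_sasa(compute_sasa(fx_bur$structure))
  for (mode in c("whole_residue", "ring_carbon")) {
    p <- accessibility_params(mode = mode)
    expect_equal(classify_tyrosines(fx_exp$structure, sasa_exp,
                                    p)$n_modifiable, 1L)
    expect_equal(classify_tyrosines(fx_bur$structure, sasa_bur,
                                    p)$n_modifiable, 0L)
  }
})

test_that("classification rejects mismatched SASA and warns on no tyrosines", {
  fx <- build_fixture("exposed_tyr")
  other <- build_fixture("helix")
  sasa_other <- relative_sasa(compute_sasa(other$structure))
  expect_error(classify_tyrosines(fx$structure, sasa_other),
               "atom keys differ")
  sasa <- relative_sasa(compute_sasa(other$structure))
  expect_warning(rep0 <- classify_tyrosines(other$structure, sasa),
                 "no tyrosines")
  expect_equal(rep0$n_total, 0L)
  expect_equal(rep0$n_modifiable, 0L)
})

test_that("apply_dopa adds one in-plane oxygen per residue and renames", {
  fx <- build_fixture("exposed_tyr")
  st <- fx$structure
  expect_identical(apply_dopa(st, character(0)), st)

  mod <- apply_dopa(st, "A:2: ")
  expect_equal(nrow(mod$atoms), nrow(st$atoms) + 1L)
  pre_keys <- atom_keys(st)
  expect_equal(
    as.matrix(mod$atoms[match(pre_keys, atom_keys(mod)), c("x", "y", "z")]),
    as.matrix(st$atoms[, c("x", "y", "z")]),
    ignore_attr = TRUE)
  res2 <- mod$atoms[residue_keys(mod) == "A:2: ", ]
  expect_true(all(res2$resname == "DAH"))
  new_o <- res2[res2$name == "OH3", ]
  ce1 <- res2[res2$name == "CE1", ]
  d <- sqrt(sum((as.numeric(new_o[, c("x", "y", "z")]) -
                   as.numeric(ce1[, c("x", "y", "z")]))^2))
  expect_equal(d, 1.36, tolerance = 0.01 / 1.36)
  ring <- as.matrix(res2[res2$name %in%
                           c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                         c("x", "y", "z")])
  centered <- sweep(ring, 2, colMeans(ring), "-")
  nrm <- svd(centered)$v[, 3]
  off_plane <- abs(sum((as.numeric(new_o[, c("x", "y", "z")]) -
                          colMeans(ring)) * nrm))
  expect_lt(off_plane, 0.05)
})

test_that("apply_dopa validates keys and rejects re-application", {
  fx <- build_fixture("exposed_tyr")
  expect_error(apply_dopa(fx$structure, "A:99: "), "not found")
  expect_error(apply_dopa(fx$structure, "A:1: "), "not tyrosine")
  mod <- apply_dopa(fx$structure, "A:2: ")
  expect_error(apply_dopa(mod, "A:2: "), "already DOPA")
})

test_that("added oxygens agree with the chemical-convention mass bookkeeping", {
  fx <- build_fixture(fixture_spec("toy_chimera", list(k = 3L, m = 1L)))
  out <- modification_pipeline(fx$structure)
  n_added <- nrow(out$structure$atoms) - nrow(fx$structure$atoms)
  chem <- modified_mass(20, out$report$n_modifiable, mass_model("chemical"))
  expect_equal(n_added, chem$n)  # one oxygen atom per DOPA in-structure
  paper <- modified_mass(20, out$report$n_modifiable, mass_model("paper"))
  expect_equal(paper$n, 2L * n_added)
})

test_that("pipeline finds the constructed exposed count and fraction", {
  fx <- build_fixture(fixture_spec("toy_chimera", list(k = 4L, m = 3L)))
  out <- modification_pipeline(fx$structure)
  expect_equal(out$report$n_total, 7L)
  expect_equal(out$report$n_modifiable, 4L)
  expect_equal(out$report$fraction, 4 / 7)
  expect_equal(nrow(out$structure$atoms), nrow(fx$structure$atoms) + 4L)

  no_tyr <- build_fixture("helix")
  out0 <- modification_pipeline(no_tyr$structure)
  expect_equal(out0$report$n_total, 0L)
  expect_identical(out0$structure, no_tyr$structure)
})

test_that("raising the threshold never increases the modifiable count", {
  fx <- build_fixture(fixture_spec("toy_chimera", list(k = 3L, m = 2L)))
  sasa <- relative_sasa(compute_sasa(fx$structure))
  counts <- vapply(seq(0.05, 0.95, by = 0.1), function(thr) {
    classify_tyrosines(fx$structure, sasa,
                       accessibility_params(threshold = thr))$n_modifiable
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("report is ordered by chain then residue number with chain counts", {
  fx <- build_fixture(fixture_spec("toy_chimera", list(k = 2L, m = 2L)))
  sasa <- relative_sasa(compute_sasa(fx$structure))
  rep <- classify_tyrosines(fx$structure, sasa)
  expect_false(is.unsorted(rep$per_tyrosine$resseq))
  cc <- rep$per_chain_counts
  expect_equal(sum(cc$total), rep$n_total)
  expect_equal(sum(cc$modifiable), rep$n_modifiable)
})
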