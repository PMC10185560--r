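test_that("the shipped catalog loads six pathways with resolvable steps", {
  cat6 <- reference_catalog()
  expect_length(cat6$pathways, 6L)
  expect_setequal(names(cat6$pathways), paste0("P", 1:6))
  for (p in cat6$pathways)
    expect_true(all(p$steps %in% names(cat6$reactions)), info = p$id)
  # printed energies carried verbatim; unprinted steps explicit unknowns
  expect_equal(cat6$reactions$rgcs_nadh$ref_energy, -1.2)
  expect_equal(cat6$reactions$lip_dtt$ref_energy, -7.4)
  expect_true(is.na(cat6$reactions$aox$ref_energy))
})

test_that("catalog validation names the offender", {
  rx <- data.frame(id = "r1", name = "r1", equation = "A = B",
                   ref_energy_kj_mol = 0, ref_ph = 7.5,
                   ref_ionic_strength = 0.2, source = "user")
  pw_bad <- data.frame(id = "p1", name = "p1", step_ids = "r1;rx99",
                       description = "")
  expect_error(load_catalog(rx, pw_bad), "rx99")
  pw_dup <- data.frame(id = c("p1", "p1"), name = "p", step_ids = "r1",
                       description = "")
  expect_error(load_catalog(rx, pw_dup), "duplicate")
  # empty pathway table: empty catalog, no error
  empty <- load_catalog(rx, pw_bad[0, ])
  expect_length(empty$pathways, 0L)
})

test_that("pathway profiles accumulate, classify, and locate the bottleneck", {
  cat3 <- toy_catalog()
  p <- profile_pathway(cat3$pathways$gly_dtt, cat3)
  expect_equal(p$step_energies, c(-0.6, -7.4))
  expect_equal(p$cumulative, c(-0.6, -8.0))
  expect_equal(p$overall, -8.0)
  expect_true(p$feasible)
  expect_equal(p$bottleneck_index, 1L)
  # an uphill step above the threshold flips feasibility
  hill <- profile_pathway(cat3$pathways$hill, cat3, feasibility_threshold = 20)
  expect_false(hill$feasible)
  expect_equal(hill$bottleneck_index, 1L)
  expect_equal(hill$overall, 25)
  # single downhill step
  solo <- profile_pathway(pathway("solo", steps = "red_dtt"), cat3)
  expect_equal(solo$overall, -7.4)
  expect_true(solo$feasible)
})

test_that("reductant substitution drops the pathway overall from -1.2 to -8.0", {
  cat3 <- toy_catalog()
  nadh <- profile_pathway(cat3$pathways$gly_nadh, cat3)
  dtt <- profile_pathway(cat3$pathways$gly_dtt, cat3)
  expect_equal(nadh$overall, -1.2)
  expect_equal(dtt$overall, -8.0)
  # the variants differ in exactly one step and by (-7.4) - (-0.6)
  expect_equal(sum(cat3$pathways$gly_nadh$steps != cat3$pathways$gly_dtt$steps), 1L)
  expect_equal(dtt$overall - nadh$overall, -6.8)
})

test_that("unknown-energy steps give a partial profile, never silent zeros", {
  cat6 <- reference_catalog()
  p6 <- profile_pathway(cat6$pathways$P6, cat6)
  expect_true(p6$partial)
  expect_true(anyNA(p6$step_energies))
  expect_true(is.na(p6$overall))
  expect_true(is.na(p6$feasible))
  # the known rGCS step is still reported
  known <- which(p6$step_ids == "rgcs_dtt")
  expect_equal(p6$step_energies[known], -8.0)
})

test_that("sign reversal negates the overall and relocates the bottleneck", {
  cat3 <- toy_catalog()
  p <- profile_pathway(cat3$pathways$hill, cat3)
  rev_rx <- data.frame(id = c("barrier", "downhill"), name = "rev",
                       equation = c("B = A", "C = B"),
                       ref_energy_kj_mol = c(-30, 5), ref_ph = 7.5,
                       ref_ionic_strength = 0.2, source = "user")
  rev_pw <- data.frame(id = "hill", name = "rev", step_ids = "barrier;downhill",
                       description = "")
  p_rev <- profile_pathway(load_catalog(rev_rx, rev_pw)$pathways$hill,
                           load_catalog(rev_rx, rev_pw))
  expect_equal(p_rev$overall, -p$overall)
  expect_equal(p_rev$bottleneck_index, 2L)  # formerly most-negative step
})

test_that("permuting steps changes the profile order but not the sum", {
  cat3 <- toy_catalog()
  fwd <- profile_pathway(pathway("a", steps = c("barrier", "downhill")), cat3)
  rev <- profile_pathway(pathway("b", steps = c("downhill", "barrier")), cat3)
  expect_equal(fwd$overall, rev$overall)
  expect_equal(sort(fwd$step_energies), sort(rev$step_energies))
})
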