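test_that("condition validates its invariants", {
  expect_error(condition(ph = 15), "ph")
  expect_error(condition(ionic_strength = -0.1), "ionic_strength")
  expect_error(condition(temperature = 0), "temperature")
  expect_error(condition(default_conc = 0), "default_conc")
  cond <- physiological_condition()
  expect_equal(cond$ph, 7.5)
  expect_equal(cond$ionic_strength, 0.20)
  expect_equal(cond$default_conc, 1e-3)
})

test_that("equation parsing yields signed stoichiometry with products positive", {
  st <- parse_equation("Hox + DTT = Hred + DTTox")
  expect_equal(st[["Hox"]], -1)
  expect_equal(st[["DTTox"]], 1)
  st2 <- parse_equation("A = 2 B")
  expect_equal(st2, c(A = -1, B = 2))
  st3 <- parse_equation("methanol + 0.5 O2 = HCHO")
  expect_equal(st3[["O2"]], -0.5)
  expect_error(parse_equation("A + B"), "=")
  expect_error(parse_equation("A = A"), "cancels")
})

test_that("concentration adjustment is the identity at the reference state", {
  rx <- reaction("r", equation = "A + B = C", ref_energy = -3.7,
                 ref_condition = standard_condition())
  expect_equal(adjust_concentrations(rx, condition(default_conc = 1)), -3.7)
  # and for shipped reference reactions at their stated 1 mM convention
  cat6 <- reference_catalog()
  for (rx in cat6$reactions) {
    if (is.na(rx$ref_energy)) next
    expect_equal(adjust_concentrations(rx, physiological_condition()),
                 rx$ref_energy, info = rx$id)
  }
})

test_that("concentration adjustment matches the hand-derived quotient value", {
  rx <- reaction("r", equation = "A = 2 B", ref_energy = 0,
                 ref_condition = standard_condition())
  # net nu = +1 over the quotient: RT ln(0.001) = -17.124 kJ/mol at 298.15 K
  got <- adjust_concentrations(rx, condition(default_conc = 1e-3))
  expect_equal(got, 8.314462618e-3 * 298.15 * log(1e-3), tolerance = 1e-10)
  expect_equal(got, -17.124, tolerance = 1e-4)
})

test_that("water and hydrogen ions never enter the quotient", {
  rx <- reaction("r", equation = "A + H2O = B + H+", ref_energy = 2,
                 ref_condition = standard_condition())
  # only A and B in the quotient; equal concentrations cancel (nu sums to 0)
  expect_equal(adjust_concentrations(rx, condition(default_conc = 1e-3)), 2)
  expect_error(
    adjust_concentrations(rx, condition(), c(`H2O` = 1)),
    "not in the quotient")
})

test_that("bad concentrations are rejected with the species named", {
  rx <- reaction("r", equation = "A = B", ref_energy = 0)
  expect_error(adjust_concentrations(rx, condition(), c(A = -1)), "A")
  expect_error(adjust_concentrations(rx, condition(), c(Z = 1)), "Z")
})

test_that("concentration adjustment is monotone in products and substrates", {
  rx <- reaction("r", equation = "S1 + 2 S2 = P1 + P2", ref_energy = -1,
                 ref_condition = standard_condition())
  cond <- condition()
  base <- adjust_concentrations(rx, cond)
  up_p <- adjust_concentrations(rx, cond, c(P1 = 5e-3))
  up_s <- adjust_concentrations(rx, cond, c(S2 = 5e-3))
  expect_gt(up_p, base)   # raising a product raises Delta_rG'
  expect_lt(up_s, base)   # raising a substrate lowers it
})

test_that("adjustment matches a brute-force term-by-term oracle on random reactions", {
  set.seed(42)
  cond <- condition(default_conc = 1)
  for (i in 1:100) {
    n_sp <- sample(2:5, 1)
    sp <- paste0("X", seq_len(n_sp))
    nu <- sample(c(-3:-1, 1:3), n_sp, replace = TRUE)
    names(nu) <- sp
    ref <- stats::runif(1, -20, 20)
    rx <- reaction(paste0("r", i), stoichiometry = nu, ref_energy = ref,
                   ref_condition = standard_condition())
    conc <- stats::setNames(stats::runif(n_sp, 1e-6, 1e-1), sp)
    got <- adjust_concentrations(rx, cond, conc)
    rt <- 8.314462618e-3 * cond$temperature
    expected <- ref
    for (s in sp) expected <- expected + rt * nu[[s]] * log(conc[[s]])
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("ionic-strength shift has its trivial zeros and the hand value", {
  expect_equal(ionic_strength_shift(c(A = 1), c(A = -2), c(A = 3),
                                    from_I = 0.20, to_I = 0.20), 0)
  expect_equal(ionic_strength_shift(c(A = -1, B = 1), c(A = 0, B = 0),
                                    c(A = 0, B = 0), 0, 0.3), 0)
  # single product, z = -1, nH = 0, 0 -> 0.25 M at 298.15 K:
  # -(1) * alpha * 0.5 / (1 + 0.8), alpha(298.15 K) = 2.91489
  got <- ionic_strength_shift(c(X = 1), c(X = -1), c(X = 0), 0, 0.25)
  alpha <- 9.20483e-3 * 298.15 - 1.28467e-5 * 298.15^2 + 4.95199e-8 * 298.15^3
  expect_equal(got, -alpha * 0.5 / 1.8, tolerance = 1e-12)
  expect_equal(got, -0.8097, tolerance = 1e-4)
  expect_error(ionic_strength_shift(c(X = 1), charges = c(Y = 1),
                                    n_hydrogen = c(X = 0), 0, 0.1),
               "missing charge")
})

test_that("step substitution is exact Hess-law arithmetic and invertible", {
  expect_identical(substitute_step(-1.2, -0.6, -7.4), -8.0)
  expect_identical(substitute_step(5, -3, -3), 5)
  expect_identical(substitute_step(0, -5, -5), 0)
  set.seed(7)
  for (i in 1:20) {
    x <- stats::runif(1, -50, 50); a <- stats::runif(1, -50, 50)
    b <- stats::runif(1, -50, 50)
    expect_equal(substitute_step(substitute_step(x, a, b), b, a), x,
                 tolerance = 1e-12)
  }
})

test_that("flux split obeys the flux-force relation", {
  expect_equal(flux_split(0)$forward_fraction, 0.5)
  fs <- flux_split(-1.2)
  expect_equal(fs$flux_ratio, exp(1.2 / (8.314462618e-3 * 298.15)),
               tolerance = 1e-12)
  expect_equal(fs$reverse_fraction, 0.381, tolerance = 1e-3)
  expect_equal(flux_split(10)$forward_fraction, 0.0174, tolerance = 1e-2)
  expect_equal(fs$forward_fraction + fs$reverse_fraction, 1)
  expect_equal(fs$flux_ratio, fs$forward_fraction / fs$reverse_fraction,
               tolerance = 1e-12)
})

test_that("flux split is symmetric, monotone, and saturates without overflow", {
  dgs <- seq(-40, 40, by = 2.5)
  fwd <- vapply(dgs, function(d) flux_split(d)$forward_fraction, numeric(1))
  expect_true(all(diff(fwd) < 0))            # strictly decreasing in Delta_rG'
  for (d in c(-12.3, -1.2, 0, 0.7, 25)) {
    expect_equal(flux_split(d)$forward_fraction +
                   flux_split(-d)$forward_fraction, 1, tolerance = 1e-12)
  }
  expect_equal(flux_split(-1e6)$forward_fraction, 1)
  expect_equal(flux_split(1e6)$forward_fraction, 0)
  expect_error(flux_split(NaN), "finite")
  expect_error(flux_split(-1, temperature = 0), "temperature")
})
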