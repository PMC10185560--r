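test_that("time courses validate their invariants", {
  expect_error(time_course(c(0, 10), c(0)), "equal length")
  expect_error(time_course(c(5), c(1)), "at least 2")
  expect_error(time_course(c(0, 10, 10), c(0, 1, 2)), "strictly increasing")
  expect_error(time_course(c(0, 10), c(0, -1)), "non-negative")
})

test_that("initial-rate fit recovers an exact line and its report units", {
  tc <- time_course(c(0, 10, 20), c(0, 0.064, 0.128))
  fit <- fit_initial_rate(tc)
  expect_equal(fit$rate_um_min, 6.4, tolerance = 1e-9)
  expect_equal(fit$intercept_mm, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # noiseless slope reproduction across a rate grid
  for (r in c(0.1, 1.9, 75)) {
    fit_r <- fit_initial_rate(linear_course(r))
    expect_equal(fit_r$rate_um_min, r, tolerance = 1e-9)
  }
})

test_that("flat and decreasing courses are flagged, not hidden", {
  flat <- fit_initial_rate(time_course(c(0, 5, 10), c(2, 2, 2)))
  expect_equal(flat$rate_um_min, 0)
  expect_true(is.na(flat$r_squared))
  expect_true("constant_concentration" %in% flat$flags)
  down <- fit_initial_rate(time_course(c(0, 5, 10), c(2, 1.5, 1)))
  expect_lt(down$rate_um_min, 0)
  expect_true("nonpositive_rate" %in% down$flags)
})

test_that("window selection stops before the plateau", {
  # linear to 16 mM at 80 uM/min, then flat
  times <- seq(0, 400, by = 50)
  concs <- pmin(0.08 * times, 16)
  fit <- fit_initial_rate(time_course(times, concs))
  expect_equal(fit$rate_um_min, 80, tolerance = 1)
  expect_lt(fit$n_points, length(times))
  expect_error(fit_initial_rate(time_course(times, concs), window = 1),
               "at least 2")
  by_min <- fit_initial_rate(time_course(times, concs),
                             window = list(minutes = 150))
  expect_equal(by_min$n_points, 4L)
})

test_that("carbon yield reproduces the printed percentages and stays linear", {
  gly_hcho <- yield_spec("glycine", "formaldehyde", 1)
  ser_meoh <- yield_spec("serine", "methanol", 2)
  expect_equal(carbon_yield(15.5, 20, gly_hcho)$percent_report, 78L)
  expect_equal(carbon_yield(15.5, 20, gly_hcho)$percent, 77.5)
  expect_equal(carbon_yield(7.5, 50, ser_meoh)$percent_report, 30L)
  expect_equal(carbon_yield(0, 20, gly_hcho)$percent, 0)
  # linear in product, inversely linear in substrate, never negative
  y1 <- carbon_yield(5, 20, gly_hcho)$percent
  expect_equal(carbon_yield(10, 20, gly_hcho)$percent, 2 * y1)
  expect_equal(carbon_yield(5, 40, gly_hcho)$percent, y1 / 2)
  expect_error(carbon_yield(5, 0, gly_hcho), "substrate")
  expect_error(yield_spec("a", "b", 0.5), "integer")
})

test_that("molar masses match independent hand computation", {
  expect_equal(compound_mass("C2H5NO2")$molar_mass, 75.07, tolerance = 0.01)
  expect_equal(compound_mass("C3H7NO3")$molar_mass, 105.09, tolerance = 0.01)
  expect_equal(compound_mass("C3H4O3")$molar_mass, 88.06, tolerance = 0.01)
  expect_error(compound_mass("C2Qq5"), "Qq|parse")
})

test_that("mM to g/L conversion reproduces printed titer pairings and is additive", {
  expect_equal(mm_to_g_per_l(15.5, "glycine")$g_per_l_report, 1.2)
  expect_equal(mm_to_g_per_l(6.9, "pyruvate")$g_per_l_report, 0.6)
  expect_equal(mm_to_g_per_l(0, "glycine")$g_per_l, 0)
  a <- mm_to_g_per_l(3.2, "serine")$g_per_l
  b <- mm_to_g_per_l(4.3, "serine")$g_per_l
  expect_equal(mm_to_g_per_l(7.5, "serine")$g_per_l, a + b, tolerance = 1e-12)
  # salt/free-acid forms are configurable through an explicit formula
  expect_gt(mm_to_g_per_l(1, "C3H3O3Na")$molar_mass,
            mm_to_g_per_l(1, "pyruvate")$molar_mass)
})

test_that("report rounding is half-up, matching the printed pairings", {
  expect_equal(round_half_up(77.5), 78)
  expect_equal(round_half_up(85.5), 86)
  expect_equal(round_half_up(1.164, 1), 1.2)
  expect_equal(round_half_up(-2.5), -3)  # away from zero
})

test_that("fold change and specific fixation rate are guarded divisions", {
  expect_equal(fold_change(6.4, 0.1), 64)
  expect_equal(fold_change(1.9, 0.1), 19)
  expect_equal(fold_change(3.3, 3.3), 1)
  expect_error(fold_change(5, 0), "absolute rates")
  expect_equal(specific_fixation_rate(100, 10, 1), 10)
  expect_equal(specific_fixation_rate(100, 10, 2),
               specific_fixation_rate(100, 10, 1) / 2)
  expect_error(specific_fixation_rate(100, 0, 1), "positive")
  # documented back-solved enzyme mass for the air-capture run:
  # 17.1 mM in 10 mL over 5.5 h with 7.643 mg total enzyme
  expect_equal(specific_fixation_rate(171000, 330, 7.643), 67.8,
               tolerance = 1e-3)
})

test_that("rate recovery from noisy synthetic courses is accurate", {
  # 200 seeded courses at 75 uM/min, 2% CV: mean recovered within 5%
  rates <- vapply(1:200, function(s) {
    tc <- gen_time_course(seed = s, n_points = 8, true_rate = 75,
                          plateau = 16, noise_cv = 0.02)
    fit_initial_rate(tc)$rate_um_min
  }, numeric(1))
  expect_lt(abs(mean(rates) - 75) / 75, 0.05)
  # rate grid 1-100 uM/min, CV 2-5%: median relative error < 3%
  set.seed(11)
  grid <- data.frame(rate = stats::runif(200, 1, 100),
                     cv = stats::runif(200, 0.02, 0.05))
  rel_err <- vapply(seq_len(nrow(grid)), function(i) {
    tc <- gen_time_course(seed = 1000 + i, n_points = 8,
                          true_rate = grid$rate[i], plateau = 1e6,
                          noise_cv = grid$cv[i])
    abs(fit_initial_rate(tc)$rate_um_min - grid$rate[i]) / grid$rate[i]
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.03)
})
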