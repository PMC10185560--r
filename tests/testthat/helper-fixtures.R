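# Shared builders for small in-code fixtures.

# A tiny catalog with fully known energies, built in code (no files):
# the two rGCS reductant variants share every step but the re-reduction.
toy_catalog <- function() {
  rx <- data.frame(
    id = c("core", "red_nadh", "red_dtt", "barrier", "downhill"),
    name = c("rGCS minus re-reduction", "lipoamide/NADH", "lipoamide/DTT",
             "uphill step", "downhill step"),
    equation = c("CO2 + CH2THF + NH3 + Hred = glycine + THF + Hox",
                 "Hox + NADH = Hred + NAD",
                 "Hox + DTT = Hred + DTTox",
                 "A = B", "B = C"),
    ref_energy_kj_mol = c(-0.6, -0.6, -7.4, 30, -5),
    ref_ph = 7.5, ref_ionic_strength = 0.20,
    source = c("derived", "reference", "reference", "user", "user"))
  pw <- data.frame(
    id = c("gly_nadh", "gly_dtt", "hill"),
    name = c("rGCS with NADH", "rGCS with DTT", "barrier pathway"),
    step_ids = c("core;red_nadh", "core;red_dtt", "barrier;downhill"),
    description = "")
  load_catalog(rx, pw)
}

# Exact linear time course at a given rate (uM/min), mM scale.
linear_course <- function(rate_um_min, times = c(0, 10, 20), ...) {
  time_course(times, rate_um_min / 1000 * times, ...)
}

glycine_246 <- function() {
  fragment_spec("glycine", 246, c("carboxyl_CO2", "methylene_HCHO"))
}
glycine_218 <- function() fragment_spec("glycine", 218, "methylene_HCHO")
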