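# Direct-air-capture bookkeeping and closed-system carbonate speciation.

#' Molar mass of CO2 used for gravimetric conversion, g/mol
#' @keywords internal
CO2_MOLAR_MASS <- 44.01

#' Record of a CO2 capture run into alkaline solution
#'
#' @param solution_volume Absorber volume, L, > 0.
#' @param base_molarity Strong-base concentration, mol/L, > 0.
#' @param co2_captured CO2 absorbed, mol, >= 0. Supply either directly or via
#'   `mass_gain_g` (gravimetric mass gain divided by 44.01 g/mol).
#' @param duration Capture duration, hours, > 0.
#' @param mass_gain_g Optional gravimetric mass gain, g.
#' @return Object of class `rgcs_capture_record`. A capture exceeding the
#'   2:1 stoichiometric capacity of the base (full conversion to carbonate
#'   requires 2 OH- per CO2; up to 1 CO2 per OH- as bicarbonate) triggers a
#'   warning, not an error.
#' @examples
#' capture_record(0.020, 1, co2_captured = 0.004, duration = 72)
#' @export
capture_record <- function(solution_volume, base_molarity, co2_captured = NULL,
                           duration = 1, mass_gain_g = NULL) {
  if (!is.finite(solution_volume) || solution_volume <= 0)
    stop("`solution_volume` must be > 0 (L)")
  if (!is.finite(base_molarity) || base_molarity <= 0)
    stop("`base_molarity` must be > 0 (mol/L)")
  if (!is.finite(duration) || duration <= 0) stop("`duration` must be > 0 (h)")
  if (is.null(co2_captured)) {
    if (is.null(mass_gain_g)) stop("give `co2_captured` (mol) or `mass_gain_g` (g)")
    if (!is.finite(mass_gain_g) || mass_gain_g < 0)
      stop("`mass_gain_g` must be >= 0")
    co2_captured <- mass_gain_g / CO2_MOLAR_MASS
  }
  if (!is.finite(co2_captured) || co2_captured < 0)
    stop("`co2_captured` must be >= 0 (mol)")
  capacity <- base_molarity * solution_volume   # mol CO2 as bicarbonate
  if (co2_captured > capacity)
    warning(sprintf(
      "captured %.4g mol exceeds the bicarbonate capacity of the base (%.4g mol)",
      co2_captured, capacity))
  structure(list(solution_volume = solution_volume,
                 base_molarity = base_molarity,
                 co2_captured = co2_captured, duration = duration),
            class = "rgcs_capture_record")
}

#' @export
print.rgcs_capture_record <- function(x, ...) {
  cat(sprintf("<capture> %.3g mol CO2 in %.3g L of %.3g M base over %.3g h (%.3g mM)\n",
              x$co2_captured, x$solution_volume, x$base_molarity, x$duration,
              1000 * captured_concentration(x)))
  invisible(x)
}

#' Captured CO2 as bicarbonate-equivalent concentration
#'
#' @param rec A [capture_record()].
#' @return mol/L of bicarbonate equivalents (`co2_captured / solution_volume`).
#' @examples
#' rec <- capture_record(0.020, 1, co2_captured = 0.004, duration = 72)
#' captured_concentration(rec) * 1000  # 200 mM
#' @export
captured_concentration <- function(rec) {
  stopifnot(inherits(rec, "rgcs_capture_record"))
  rec$co2_captured / rec$solution_volume
}

#' Dilution of a capture stock to a working concentration
#'
#' @param stock Stock concentration, mol/L, > 0.
#' @param target Target concentration, mol/L, with `0 < target <= stock`.
#' @return List: `factor` (stock/target), `stock_volume` and
#'   `diluent_volume` per unit final volume. Mole bookkeeping is exact:
#'   `stock * stock_volume == target * 1`.
#' @examples
#' dilute(0.200, 0.050)$factor  # 4
#' @export
dilute <- function(stock, target) {
  if (!is.finite(stock) || stock <= 0) stop("`stock` must be > 0 (mol/L)")
  if (!is.finite(target) || target <= 0) stop("`target` must be > 0 (mol/L)")
  if (target > stock)
    stop("`target` (", target, ") exceeds `stock` (", stock,
         "): cannot dilute upward")
  factor <- stock / target
  list(factor = factor, stock_volume = 1 / factor,
       diluent_volume = 1 - 1 / factor)
}

#' pH of a closed potassium-hydroxide/carbonate solution
#'
#' Solves the charge balance of a closed system containing a strong base at
#' `total_base` mol/L and total dissolved inorganic carbon `total_carbon`
#' mol/L, with carbonate speciation governed by `pKa1`/`pKa2`:
#' `CB + [H+] = [OH-] + [HCO3-] + 2[CO3^2-]`. Root found by bisection on pH
#' in \[0, 14\] to a charge imbalance below 1e-10 M.
#'
#' @param total_base Strong-base cation concentration, mol/L, >= 0.
#' @param total_carbon Total inorganic carbon, mol/L, >= 0.
#' @param pKa1,pKa2 Carbonic-acid dissociation constants (defaults 6.35,
#'   10.33 at 25 C).
#' @param pKw Water ion product exponent (default 14).
#' @return pH (dimensionless).
#' @examples
#' carbonate_ph(0.3, 0.2)   # equimolar HCO3-/CO3^2- buffer: ~pKa2
#' carbonate_ph(1, 0.2)     # excess strong base: strongly alkaline
#' @export
carbonate_ph <- function(total_base, total_carbon, pKa1 = 6.35, pKa2 = 10.33,
                         pKw = 14) {
  if (!is.finite(total_base) || total_base < 0)
    stop("`total_base` must be >= 0 (mol/L)")
  if (!is.finite(total_carbon) || total_carbon < 0)
    stop("`total_carbon` must be >= 0 (mol/L)")
  Ka1 <- 10^(-pKa1); Ka2 <- 10^(-pKa2); Kw <- 10^(-pKw)
  imbalance <- function(ph) {
    H <- 10^(-ph); OH <- Kw / H
    denom <- H^2 + Ka1 * H + Ka1 * Ka2
    total_base + H - OH - total_carbon * (Ka1 * H + 2 * Ka1 * Ka2) / denom
  }
  lo <- 0; hi <- 14
  flo <- imbalance(lo); fhi <- imbalance(hi)
  tol <- 1e-10
  if (flo * fhi > 0) {
    # no interior root: accept an endpoint whose residual is negligible
    if (abs(fhi) < tol) return(hi)
    if (abs(flo) < tol) return(lo)
    stop("no pH root in [0, 14] for total_base = ", total_base,
         ", total_carbon = ", total_carbon)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- imbalance(mid)
    if (abs(fm) < tol && (hi - lo) < 1e-12) break
    # imbalance decreases with pH
    if (fm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
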