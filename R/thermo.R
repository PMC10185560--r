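# Transformed Gibbs-energy arithmetic for biochemical reactions.

#' Gas constant, kJ mol^-1 K^-1
#' @keywords internal
RGAS <- 8.314462618e-3

# Species never entering the concentration quotient: water activity is taken
# as 1 and H+ is absorbed into the transformed (fixed-pH) energies.
.quotient_excluded <- c("h2o", "water", "h+", "h")

#' Evaluation condition for transformed reaction energies
#'
#' A condition bundles the intensive variables under which a transformed
#' reaction Gibbs energy (Delta_r G') is stated or evaluated: pH, ionic
#' strength, temperature, and the concentration assigned by convention to any
#' reactant without an explicit value.
#'
#' @param ph pH, dimensionless, in \[0, 14\].
#' @param ionic_strength Ionic strength, mol/L, non-negative.
#' @param temperature Temperature, kelvin, positive. Default 298.15 K.
#' @param default_conc Concentration (mol/L) applied to every reactant that is
#'   not given an explicit concentration. Default 1e-3 (the 1 mM convention
#'   used for physiological pathway profiles).
#' @return An object of class `rgcs_condition`.
#' @examples
#' physiological_condition()
#' condition(ph = 7, ionic_strength = 0.1, temperature = 310.15)
#' @export
condition <- function(ph = 7.5, ionic_strength = 0.20, temperature = 298.15,
                      default_conc = 1e-3) {
  stopifnot(is.numeric(ph), length(ph) == 1L, is.finite(ph),
            is.numeric(ionic_strength), length(ionic_strength) == 1L,
            is.numeric(temperature), length(temperature) == 1L,
            is.numeric(default_conc), length(default_conc) == 1L)
  if (ph < 0 || ph > 14) stop("`ph` must lie in [0, 14], got ", ph)
  if (ionic_strength < 0) stop("`ionic_strength` must be >= 0")
  if (temperature <= 0) stop("`temperature` must be > 0 (kelvin)")
  if (default_conc <= 0) stop("`default_conc` must be > 0 (mol/L)")
  structure(list(ph = ph, ionic_strength = ionic_strength,
                 temperature = temperature, default_conc = default_conc),
            class = "rgcs_condition")
}

#' @rdname condition
#' @details `physiological_condition()` is the profiling convention used
#'   throughout the shipped pathway catalog: pH 7.5, I = 0.20 M, 298.15 K,
#'   all reactants at 1 mM.
#' @export
physiological_condition <- function() condition()

#' @rdname condition
#' @details `standard_condition()` keeps the same pH/I/T but places every
#'   reactant at the 1 M standard state.
#' @export
standard_condition <- function() condition(default_conc = 1)

#' @export
print.rgcs_condition <- function(x, ...) {
  cat(sprintf("<condition> pH %.2f, I = %.2f M, T = %.2f K, default conc %g M\n",
              x$ph, x$ionic_strength, x$temperature, x$default_conc))
  invisible(x)
}

#' Parse a reaction equation string into signed stoichiometry
#'
#' Equations are written `"Hox + DTT = Hred + DTTox"`, optionally with integer
#' or fractional coefficients (`"A = 2 B"`, `"0.5 O2"`). Products carry
#' positive coefficients, substrates negative.
#'
#' @param equation Character scalar with a single `=` separating substrates
#'   from products.
#' @return Named numeric vector of signed coefficients.
#' @examples
#' parse_equation("methanol + 0.5 O2 = HCHO + H2O2")
#' @export
parse_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L)
  sides <- strsplit(equation, "=", fixed = TRUE)[[1L]]
  if (length(sides) != 2L)
    stop("equation must contain exactly one '=': ", equation)
  parse_side <- function(txt, sign) {
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1L]])
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L)
      stop("empty reaction side in equation: ", equation)
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+)?\\s*(\\S+)$", tm))[[1L]]
      if (length(m) == 0L) stop("cannot parse term '", tm, "' in: ", equation)
      coef <- if (nzchar(m[2L])) as.numeric(m[2L]) else 1
      sp <- m[3L]
      out[sp] <- if (sp %in% names(out)) out[[sp]] + sign * coef else sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1L], -1)
  rhs <- parse_side(sides[2L], +1)
  stoich <- lhs
  for (sp in names(rhs))
    stoich[sp] <- if (sp %in% names(stoich)) stoich[[sp]] + rhs[[sp]] else rhs[[sp]]
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L)
    stop("equation cancels to nothing: ", equation)
  stoich
}

#' Biochemical reaction with a reference transformed energy
#'
#' A reaction couples signed stoichiometry over named species (products
#' positive) with a reference Delta_r G' stated at a reference [condition].
#' Reference energies are stored verbatim at their stated condition; the
#' toolkit adjusts them to other concentration sets with
#' [adjust_concentrations()], it never re-derives them from formation
#' energies.
#'
#' @param id Short identifier.
#' @param name Human-readable name.
#' @param equation Equation string, see [parse_equation()]; alternatively pass
#'   `stoichiometry` directly.
#' @param ref_energy Delta_r G' at `ref_condition`, kJ/mol. `NA` marks a step
#'   whose energy is unknown.
#' @param ref_condition [condition] at which `ref_energy` is stated.
#' @param stoichiometry Named numeric vector of signed coefficients
#'   (overrides `equation` when given).
#' @param source Provenance: `"reference"` (shipped reference value),
#'   `"derived"` (Hess-law combination of reference values), or `"user"`.
#' @return An object of class `rgcs_reaction`.
#' @examples
#' reaction("lip_dtt", "lipoamide reduction by DTT",
#'          "Hox + DTT = Hred + DTTox", ref_energy = -7.4)
#' @export
reaction <- function(id, name = id, equation = NULL, ref_energy = NA_real_,
                     ref_condition = physiological_condition(),
                     stoichiometry = NULL,
                     source = c("user", "reference", "derived")) {
  source <- match.arg(source)
  if (is.null(stoichiometry)) {
    if (is.null(equation)) stop("give either `equation` or `stoichiometry`")
    stoichiometry <- parse_equation(equation)
  } else {
    if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
      stop("`stoichiometry` must be a fully named numeric vector")
    if (any(stoichiometry == 0)) stop("stoichiometric coefficients must be nonzero")
  }
  if (length(stoichiometry) == 0L) stop("stoichiometry must be non-empty")
  stopifnot(inherits(ref_condition, "rgcs_condition"))
  structure(list(id = as.character(id), name = as.character(name),
                 equation = equation, stoichiometry = stoichiometry,
                 ref_energy = as.numeric(ref_energy),
                 ref_condition = ref_condition, source = source),
            class = "rgcs_reaction")
}

#' @export
print.rgcs_reaction <- function(x, ...) {
  en <- if (is.na(x$ref_energy)) "unknown" else sprintf("%.1f kJ/mol", x$ref_energy)
  cat(sprintf("<reaction %s> %s  [Delta_rG' = %s, %s]\n",
              x$id, x$name, en, x$source))
  invisible(x)
}

# Species of a reaction that enter the concentration quotient.
quotient_species <- function(reaction) {
  sp <- names(reaction$stoichiometry)
  sp[!(tolower(sp) %in% .quotient_excluded)]
}

#' Adjust a reaction energy to a new set of concentrations
#'
#' Applies the reaction-quotient term of transformed biochemical
#' thermodynamics,
#' \deqn{\Delta_r G' = \Delta_r G'_{ref} + RT \sum_i \nu_i \ln(c_i / c_{ref,i}),}
#' moving the stored reference energy from the concentrations of its
#' reference condition to the concentrations supplied. Water and H+ never
#' enter the quotient (water activity 1; pH is carried by the transformed
#' reference energy itself). When every quotient concentration equals its
#' reference value the stored energy is returned unchanged.
#'
#' @param reaction A [reaction()].
#' @param condition A [condition()]; supplies the temperature and the default
#'   concentration for species missing from `concentrations`.
#' @param concentrations Named numeric vector, mol/L, for any subset of the
#'   reaction's quotient species. Species not listed take
#'   `condition$default_conc`.
#' @return Delta_r G' in kJ/mol at the supplied concentrations.
#' @examples
#' rx <- reaction("demo", equation = "A = 2 B", ref_energy = 0,
#'                ref_condition = standard_condition())
#' # all species at 1 mM: 0 + RT * ln(0.001) = -17.1 kJ/mol
#' adjust_concentrations(rx, condition(), c(A = 1e-3, B = 1e-3))
#' @export
adjust_concentrations <- function(reaction, condition = physiological_condition(),
                                  concentrations = NULL) {
  stopifnot(inherits(reaction, "rgcs_reaction"),
            inherits(condition, "rgcs_condition"))
  if (is.na(reaction$ref_energy))
    stop("reaction '", reaction$id, "' has unknown reference energy")
  qs <- quotient_species(reaction)
  if (!is.null(concentrations)) {
    if (is.null(names(concentrations)) || any(!nzchar(names(concentrations))))
      stop("`concentrations` must be a named vector (mol/L)")
    unknown <- setdiff(names(concentrations), qs)
    if (length(unknown) > 0L)
      stop("concentration given for species not in the quotient of '",
           reaction$id, "': ", paste(unknown, collapse = ", "))
  }
  conc <- rep(condition$default_conc, length(qs))
  names(conc) <- qs
  if (!is.null(concentrations)) conc[names(concentrations)] <- concentrations
  bad <- names(conc)[!is.finite(conc) | conc <= 0]
  if (length(bad) > 0L)
    stop("nonpositive or missing concentration for species: ",
         paste(bad, collapse = ", "))
  nu <- reaction$stoichiometry[qs]
  rt <- RGAS * condition$temperature
  c_ref <- reaction$ref_condition$default_conc
  as.numeric(reaction$ref_energy + rt * sum(nu * log(conc / c_ref)))
}

# Alberty's temperature-dependent Debye-Hueckel coefficient,
# kJ mol^-1 M^-1/2; cubic fit valid around 273-313 K.
debye_huckel_alpha <- function(temperature) {
  9.20483e-3 * temperature - 1.28467e-5 * temperature^2 +
    4.95199e-8 * temperature^3
}

#' Ionic-strength correction for a transformed reaction energy
#'
#' Additive correction that moves a transformed reaction energy from one
#' ionic strength to another under the extended Debye--Hueckel activity model
#' in the Alberty form (B = 1.6 M^-1/2): per species the transformed
#' formation energy shifts by \eqn{-(z_i^2 - n_{H,i})\,\alpha(T)\sqrt I /
#' (1 + 1.6\sqrt I)}, and the reaction-level correction is the
#' stoichiometry-weighted sum of the per-species shifts at the target minus
#' the source ionic strength.
#'
#' @param stoichiometry Named numeric vector of signed coefficients (products
#'   positive); the correction covers exactly these species.
#' @param charges Named integer vector: formal charge z per species.
#' @param n_hydrogen Named integer vector: hydrogen-atom count per species
#'   (the pH-binding term of the transform).
#' @param from_I,to_I Source and target ionic strengths, mol/L.
#' @param temperature Kelvin.
#' @return Correction in kJ/mol to add to the energy stated at `from_I`.
#' @examples
#' ionic_strength_shift(c(X = 1), charges = c(X = -1),
#'                      n_hydrogen = c(X = 0), from_I = 0, to_I = 0.25)
#' @export
ionic_strength_shift <- function(stoichiometry, charges, n_hydrogen,
                                 from_I, to_I, temperature = 298.15) {
  stopifnot(is.numeric(from_I), is.numeric(to_I), from_I >= 0, to_I >= 0,
            temperature > 0)
  sp <- names(stoichiometry)
  missing_z <- setdiff(sp, names(charges))
  missing_h <- setdiff(sp, names(n_hydrogen))
  if (length(missing_z) > 0L)
    stop("missing charge for species: ", paste(missing_z, collapse = ", "))
  if (length(missing_h) > 0L)
    stop("missing hydrogen count for species: ", paste(missing_h, collapse = ", "))
  if (from_I == to_I) return(0)
  a <- debye_huckel_alpha(temperature)
  f <- function(I) a * sqrt(I) / (1 + 1.6 * sqrt(I))
  z <- charges[sp]
  nh <- n_hydrogen[sp]
  as.numeric(sum(stoichiometry * (-(z^2 - nh)) * (f(to_I) - f(from_I))))
}

#' Replace one step's energy inside an overall reaction energy
#'
#' Hess-law coupling: an overall Delta_r G' that contains `old_step` as one of
#' its summands is rewritten with `new_step` in its place,
#' `overall - old_step + new_step`. This is the arithmetic behind swapping
#' the NADH-dependent lipoamide re-reduction for a chemical reductant in the
#' rGCS overall energy.
#'
#' @param overall,old_step,new_step Energies in kJ/mol.
#' @return Recombined overall energy, kJ/mol.
#' @examples
#' # rGCS overall with NADH (-1.2), lipoamide/NADH step (-0.6) replaced by
#' # lipoamide/DTT (-7.4):
#' substitute_step(-1.2, -0.6, -7.4)  # -8.0
#' @export
substitute_step <- function(overall, old_step, new_step) {
  stopifnot(is.finite(overall), is.finite(old_step), is.finite(new_step))
  overall - old_step + new_step
}

#' Forward/reverse flux partition from the flux-force relation
#'
#' The flux-force relation ties the net driving force to the ratio of one-way
#' fluxes, \eqn{\Delta_r G' = -RT \ln(J^+/J^-)}, with \eqn{J^+} the flux in
#' the synthesis (forward) direction. The forward fraction of the total
#' unidirectional flux is \eqn{J^+/(J^+ + J^-)}.
#'
#' @param delta_g Delta_r G' in kJ/mol; finite.
#' @param temperature Kelvin.
#' @return An object of class `rgcs_flux_split` with fields `flux_ratio`
#'   (J+/J-), `forward_fraction`, `reverse_fraction`, `delta_g`,
#'   `temperature`.
#' @examples
#' flux_split(-1.2)   # ~62% forward, ~38% reverse
#' flux_split(-7.4)   # ~95% forward
#' @export
flux_split <- function(delta_g, temperature = 298.15) {
  stopifnot(is.numeric(delta_g), length(delta_g) == 1L,
            is.numeric(temperature), length(temperature) == 1L)
  if (!is.finite(delta_g)) stop("`delta_g` must be finite")
  if (temperature <= 0) stop("`temperature` must be > 0 (kelvin)")
  x <- -delta_g / (RGAS * temperature)
  if (x > 700) {                 # saturate rather than overflow exp()
    ratio <- Inf; fwd <- 1
  } else if (x < -700) {
    ratio <- 0; fwd <- 0
  } else {
    ratio <- exp(x)
    fwd <- ratio / (1 + ratio)
  }
  structure(list(flux_ratio = ratio, forward_fraction = fwd,
                 reverse_fraction = 1 - fwd, delta_g = delta_g,
                 temperature = temperature),
            class = "rgcs_flux_split")
}

#' @export
print.rgcs_flux_split <- function(x, ...) {
  cat(sprintf(
    "<flux split> Delta_rG' = %.2f kJ/mol at %.2f K: %.1f%% forward, %.1f%% reverse (J+/J- = %.3g)\n",
    x$delta_g, x$temperature, 100 * x$forward_fraction,
    100 * x$reverse_fraction, x$flux_ratio))
  invisible(x)
}
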