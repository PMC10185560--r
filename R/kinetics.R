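# Initial-rate estimation and titer/yield/fold-change accounting.

#' Round half away from zero
#'
#' Report rounding used for yields and g/L titers: 77.5 -> 78, 85.5 -> 86,
#' unlike base R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal digits to keep.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Concentration time course of one analyte
#'
#' @param times Sampling times, minutes, strictly increasing, length >= 2.
#' @param concs Concentrations, mM, same length, non-negative.
#' @param analyte Analyte name.
#' @param run_id Run identifier.
#' @return An object of class `rgcs_time_course`.
#' @export
time_course <- function(times, concs, analyte = "glycine", run_id = "run1") {
  stopifnot(is.numeric(times), is.numeric(concs))
  if (length(times) != length(concs))
    stop("`times` and `concs` must have equal length")
  if (length(times) < 2L) stop("a time course needs at least 2 points")
  if (anyNA(times) || anyNA(concs)) stop("times/concs must not contain NA")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing (duplicate or reversed timestamps)")
  if (any(concs < 0)) stop("`concs` must be non-negative (mM)")
  structure(list(times = as.numeric(times), concs = as.numeric(concs),
                 analyte = as.character(analyte), run_id = as.character(run_id)),
            class = "rgcs_time_course")
}

#' @export
print.rgcs_time_course <- function(x, ...) {
  cat(sprintf("<time course> %s (%s): %d points, %.0f-%.0f min, %.3g-%.3g mM\n",
              x$analyte, x$run_id, length(x$times), min(x$times), max(x$times),
              min(x$concs), max(x$concs)))
  invisible(x)
}

# OLS of y on t with explicit R^2 (NaN for a flat response).
.ols <- function(t, y) {
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  slope <- sum((t - tm) * (y - ym)) / sxx
  intercept <- ym - slope * tm
  sst <- sum((y - ym)^2)
  sse <- sum((y - intercept - slope * t)^2)
  r2 <- if (sst == 0) NaN else 1 - sse / sst
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Longest initial prefix (>= min_points) whose linear fit has R^2 >= r2_min;
# falls back to the first min_points if no prefix qualifies.
select_initial_window <- function(tc, r2_min = 0.98, min_points = 3L) {
  n <- length(tc$times)
  min_points <- min(min_points, n)
  best <- min_points
  for (k in seq(min_points, n)) {
    r2 <- .ols(tc$times[1:k], tc$concs[1:k])$r_squared
    if (is.nan(r2)) r2 <- 1       # flat data: no curvature evidence
    if (r2 >= r2_min) best <- k else break
  }
  best
}

#' Initial production rate from a time course
#'
#' Ordinary least-squares slope of concentration (mM) against time (min) over
#' an initial window, reported in uM/min. By default the window is the
#' longest initial prefix with R^2 >= 0.98 (minimum 3 points), which tracks
#' the linear rise of a production curve and stops before the plateau.
#'
#' @param tc A [time_course()].
#' @param window Either `NULL` (automatic prefix selection), an integer count
#'   of initial points, or a list `list(minutes = m)` selecting all points
#'   with `time <= m`.
#' @return Object of class `rgcs_rate_fit`: `rate_um_min`, `slope_mm_min`,
#'   `intercept_mm`, `r_squared` (NA for a perfectly flat course), `n_points`,
#'   `window_points`, `flags` (character; e.g. `"nonpositive_rate"`).
#' @examples
#' tc <- time_course(c(0, 10, 20), c(0, 0.064, 0.128))
#' fit_initial_rate(tc)$rate_um_min  # 6.4
#' @export
fit_initial_rate <- function(tc, window = NULL) {
  stopifnot(inherits(tc, "rgcs_time_course"))
  n <- length(tc$times)
  if (is.null(window)) {
    k <- select_initial_window(tc)
    idx <- seq_len(k)
  } else if (is.list(window)) {
    if (is.null(window$minutes)) stop("list window must name `minutes`")
    idx <- which(tc$times <= window$minutes)
  } else {
    if (window < 2) stop("window must select at least 2 points")
    idx <- seq_len(min(as.integer(window), n))
  }
  if (length(idx) < 2L)
    stop("window selects fewer than 2 points")
  t <- tc$times[idx]; y <- tc$concs[idx]
  fit <- .ols(t, y)
  slope <- fit$slope
  intercept <- fit$intercept
  r2 <- fit$r_squared
  flags <- character(0)
  if (all(y == y[1L])) {        # constant course: slope 0, R^2 undefined
    slope <- 0; r2 <- NA_real_
    flags <- c(flags, "constant_concentration")
  }
  if (is.nan(r2)) r2 <- NA_real_
  if (slope <= 0) flags <- c(flags, "nonpositive_rate")
  structure(list(rate_um_min = slope * 1000, slope_mm_min = slope,
                 intercept_mm = intercept, r_squared = r2,
                 n_points = length(idx), window_points = idx,
                 analyte = tc$analyte, run_id = tc$run_id, flags = flags),
            class = "rgcs_rate_fit")
}

#' @export
print.rgcs_rate_fit <- function(x, ...) {
  cat(sprintf("<rate fit> %s (%s): %.3g uM/min over %d points (R^2 = %s)%s\n",
              x$analyte, x$run_id, x$rate_um_min, x$n_points,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Yield specification: substrate equivalents per product molecule
#'
#' @param product,substrate Names.
#' @param substrate_equivalents Integer >= 1: substrate molecules consumed
#'   per product molecule (e.g. 2 methanol-derived C1 units per serine).
#' @return Object of class `rgcs_yield_spec`.
#' @export
yield_spec <- function(product, substrate, substrate_equivalents = 1L) {
  eq <- substrate_equivalents
  if (!is.numeric(eq) || length(eq) != 1L || eq < 1 || eq != round(eq))
    stop("`substrate_equivalents` must be an integer >= 1")
  structure(list(product = product, substrate = substrate,
                 substrate_equivalents = as.integer(eq)),
            class = "rgcs_yield_spec")
}

#' Carbon yield of a product on a fed substrate
#'
#' Percent of the theoretical maximum:
#' `100 * product_conc / (substrate_conc / substrate_equivalents)`. For
#' fed-batch runs `substrate_conc` is the cumulative amount fed. The report
#' value is rounded half-up to an integer percent; the unrounded value is
#' retained.
#'
#' @param product_conc Product titer, mM, >= 0.
#' @param substrate_conc Total substrate fed, mM, > 0.
#' @param spec A [yield_spec()].
#' @return List with `percent` (unrounded), `percent_report` (integer),
#'   `spec`.
#' @examples
#' carbon_yield(15.5, 20, yield_spec("glycine", "formaldehyde"))$percent_report  # 78
#' carbon_yield(7.5, 50, yield_spec("serine", "methanol", 2))$percent_report     # 30
#' @export
carbon_yield <- function(product_conc, substrate_conc, spec) {
  stopifnot(inherits(spec, "rgcs_yield_spec"))
  if (!is.finite(substrate_conc) || substrate_conc <= 0)
    stop("`substrate_conc` must be > 0 (total amount fed, mM)")
  if (!is.finite(product_conc) || product_conc < 0)
    stop("`product_conc` must be >= 0")
  pct <- 100 * product_conc / (substrate_conc / spec$substrate_equivalents)
  list(percent = pct, percent_report = as.integer(round_half_up(pct)),
       spec = spec)
}

# IUPAC 2021 standard atomic weights (abridged), g/mol.
.atomic_weights <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, Na = 22.990, K = 39.098,
                     Cl = 35.45, Si = 28.085)

#' Molar mass from an elemental formula
#'
#' @param formula Formula string such as `"C2H5NO2"` (element symbols with
#'   optional counts), or a named numeric vector of element counts.
#' @return Object of class `rgcs_compound`: `formula` (named counts),
#'   `molar_mass` (g/mol).
#' @examples
#' compound_mass("C2H5NO2")$molar_mass  # 75.07 (glycine)
#' @export
compound_mass <- function(formula) {
  if (is.character(formula)) {
    stopifnot(length(formula) == 1L)
    parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
    if (sum(nchar(parts)) != nchar(formula))
      stop("cannot parse formula: ", formula)
    counts <- numeric(0)
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      k <- sub("^[A-Za-z]+", "", p)
      k <- if (nzchar(k)) as.numeric(k) else 1
      counts[el] <- if (el %in% names(counts)) counts[[el]] + k else k
    }
  } else {
    counts <- formula
    if (is.null(names(counts))) stop("formula vector must be named by element")
  }
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown) > 0L)
    stop("no atomic weight for element(s): ", paste(unknown, collapse = ", "))
  mm <- sum(counts * .atomic_weights[names(counts)])
  structure(list(formula = counts, molar_mass = as.numeric(mm)),
            class = "rgcs_compound")
}

# Packaged compounds for the mM <-> g/L dual reporting.
.compounds <- list(
  glycine  = "C2H5NO2",
  serine   = "C3H7NO3",
  pyruvate = "C3H4O3",      # free acid; pass a formula for a salt form
  formaldehyde = "CH2O",
  methanol = "CH4O",
  co2      = "CO2"
)

#' Convert a millimolar titer to g/L
#'
#' @param conc_mm Concentration, mM, >= 0.
#' @param compound Compound name from the packaged table (`"glycine"`,
#'   `"serine"`, `"pyruvate"`, ...), a formula string, or an
#'   [compound_mass()] object.
#' @return List with `g_per_l` (unrounded), `g_per_l_report` (one decimal,
#'   half-up), `molar_mass`.
#' @examples
#' mm_to_g_per_l(15.5, "glycine")$g_per_l_report  # 1.2
#' mm_to_g_per_l(6.9, "pyruvate")$g_per_l_report  # 0.6
#' @export
mm_to_g_per_l <- function(conc_mm, compound) {
  if (!is.finite(conc_mm) || conc_mm < 0) stop("`conc_mm` must be >= 0")
  cmp <- if (inherits(compound, "rgcs_compound")) {
    compound
  } else if (is.character(compound) && compound %in% names(.compounds)) {
    compound_mass(.compounds[[compound]])
  } else if (is.character(compound)) {
    compound_mass(compound)   # treat as a formula; unknown symbols error out
  } else {
    stop("unknown compound: ", deparse(compound))
  }
  g <- conc_mm * cmp$molar_mass / 1000
  list(g_per_l = g, g_per_l_report = round_half_up(g, 1),
       molar_mass = cmp$molar_mass)
}

#' Fold change between two rates
#'
#' @param rate_new,rate_old Rates in the same units; `rate_old` must be > 0
#'   (with a zero baseline report absolute rates instead).
#' @return `rate_new / rate_old`.
#' @examples
#' fold_change(6.4, 0.1)  # 64
#' @export
fold_change <- function(rate_new, rate_old) {
  if (!is.finite(rate_old) || rate_old <= 0)
    stop("`rate_old` must be > 0; with a zero baseline report absolute rates")
  if (!is.finite(rate_new)) stop("`rate_new` must be finite")
  rate_new / rate_old
}

#' Specific C1-fixation rate
#'
#' Product formed per unit time per unit total enzyme mass, the
#' cross-pathway comparison unit for cell-free CO2-fixation systems.
#'
#' @param product_formed Product, nmol, > 0.
#' @param minutes Duration, min, > 0.
#' @param enzyme_mass Total enzyme, mg, > 0.
#' @return Rate in nmol/min/mg.
#' @examples
#' specific_fixation_rate(100, 10, 1)  # 10
#' @export
specific_fixation_rate <- function(product_formed, minutes, enzyme_mass) {
  vals <- c(product_formed = product_formed, minutes = minutes,
            enzyme_mass = enzyme_mass)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0L)
    stop("inputs must be positive: ", paste(bad, collapse = ", "))
  product_formed / minutes / enzyme_mass
}
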