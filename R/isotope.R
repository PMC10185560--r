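# 13C SIM fragment mass-shift modelling and enrichment inversion.
#
# Nominal (integer) mass arithmetic only: each 13C-labeled carbon in a
# fragment shifts the nominal m/z by +1 with probability equal to its source
# pool's enrichment. Natural-abundance correction for the other atoms of the
# dansyl/TBDMS derivative is out of scope; at the near-complete labeling
# these cascades produce, nominal shifts carry the signal.

#' Carbon-source pools recognised by the labeling model
#'
#' `carboxyl_CO2`: the carboxyl carbon fixed from the CO2/bicarbonate pool.
#' `methylene_HCHO`: the alpha/methylene carbon delivered by formaldehyde via
#' 5,10-CH2-THF. `beta_THF`: the serine beta carbon, also delivered as a
#' CH2-THF unit and hence drawing on the formaldehyde pool.
#' @keywords internal
.carbon_sources <- c("carboxyl_CO2", "methylene_HCHO", "beta_THF")

# Pool feeding each carbon source.
.source_pool <- c(carboxyl_CO2 = "co2", methylene_HCHO = "hcho",
                  beta_THF = "hcho")

#' GC-MS SIM fragment specification
#'
#' @param analyte Analyte name.
#' @param base_mz Nominal m/z of the unlabeled fragment, positive integer.
#' @param carbon_sources Character vector, subset of
#'   `c("carboxyl_CO2", "methylene_HCHO", "beta_THF")`: the labeled-carbon
#'   positions the fragment retains after derivatization.
#' @return Object of class `rgcs_fragment`.
#' @examples
#' fragment_spec("glycine", 246, c("carboxyl_CO2", "methylene_HCHO"))
#' @export
fragment_spec <- function(analyte, base_mz, carbon_sources) {
  if (!is.numeric(base_mz) || length(base_mz) != 1L || base_mz <= 0 ||
      base_mz != round(base_mz))
    stop("`base_mz` must be a positive integer")
  carbon_sources <- as.character(carbon_sources)
  bad <- setdiff(carbon_sources, .carbon_sources)
  if (length(bad) > 0L)
    stop("unknown carbon source(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.carbon_sources, collapse = ", "), ")")
  if (anyDuplicated(carbon_sources)) stop("duplicate carbon sources")
  structure(list(analyte = as.character(analyte), base_mz = as.integer(base_mz),
                 carbon_sources = carbon_sources),
            class = "rgcs_fragment")
}

#' @export
print.rgcs_fragment <- function(x, ...) {
  cat(sprintf("<fragment> %s m/z %d [%s]\n", x$analyte, x$base_mz,
              paste(x$carbon_sources, collapse = ", ")))
  invisible(x)
}

#' Per-pool 13C enrichment state
#'
#' @param co2 Fraction of the CO2/bicarbonate pool that is 13C, in \[0, 1\].
#' @param hcho Fraction of the formaldehyde pool that is 13C, in \[0, 1\].
#' @return Object of class `rgcs_labels`.
#' @export
label_state <- function(co2 = 0, hcho = 0) {
  for (v in c(co2 = co2, hcho = hcho))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("enrichments must lie in [0, 1]")
  structure(list(co2 = co2, hcho = hcho), class = "rgcs_labels")
}

# Labeling probability for each carbon source of a fragment.
source_probs <- function(spec, labels) {
  vapply(spec$carbon_sources,
         function(src) labels[[.source_pool[[src]]]], numeric(1))
}

#' Expected isotopologue distribution of a SIM fragment
#'
#' Each labeled carbon retained by the fragment adds +1 to the nominal m/z
#' independently with probability equal to its pool's enrichment; the
#' distribution over shifts 0..n is the Poisson-binomial convolution of those
#' Bernoulli labels.
#'
#' @param spec A [fragment_spec()].
#' @param labels A [label_state()].
#' @return Named numeric vector of probabilities over m/z `base_mz` ..
#'   `base_mz + n_carbons`; sums to 1. The name of each element is its m/z.
#' @examples
#' gly <- fragment_spec("glycine", 246, c("carboxyl_CO2", "methylene_HCHO"))
#' fragment_mz(gly, label_state(co2 = 1, hcho = 1))  # all mass at 248
#' @export
fragment_mz <- function(spec, labels) {
  stopifnot(inherits(spec, "rgcs_fragment"), inherits(labels, "rgcs_labels"))
  p <- source_probs(spec, labels)
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  names(dist) <- spec$base_mz + seq_along(dist) - 1L
  dist
}

#' Estimate pool enrichments from SIM intensities
#'
#' Least-squares inversion of the [fragment_mz()] forward model. Intensities
#' for one or several fragments of the same analyte are normalised to
#' fractions per fragment and fitted jointly; a pool whose carbon appears in
#' no supplied fragment is reported as `NA` (undetermined), never as zero.
#' With a single two-carbon fragment drawing on both pools the two
#' enrichments are only jointly identified (the shift distribution is
#' symmetric in them); supplying a second fragment that lacks one of the
#' carbons (e.g. the glycine m/z 218 fragment, which has lost the carboxyl
#' carbon) resolves the assignment.
#'
#' @param intensities For a single fragment: named numeric vector of counts
#'   keyed by m/z. For several fragments: a list of such vectors, parallel to
#'   `specs`.
#' @param specs A [fragment_spec()] or list of them.
#' @return Object of class `rgcs_enrichment`: `co2`, `hcho` (estimates or
#'   `NA` when undetermined), `sse` (residual sum of squares on the fraction
#'   scale), `identifiable` (named logical).
#' @examples
#' gly246 <- fragment_spec("glycine", 246, c("carboxyl_CO2", "methylene_HCHO"))
#' enrichment_from_sim(c(`246` = 0, `247` = 0, `248` = 1000), gly246)
#' @export
enrichment_from_sim <- function(intensities, specs) {
  if (inherits(specs, "rgcs_fragment")) {
    specs <- list(specs)
    intensities <- list(intensities)
  }
  stopifnot(length(intensities) == length(specs), length(specs) >= 1L)
  obs <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    stopifnot(inherits(sp, "rgcs_fragment"))
    y <- intensities[[i]]
    if (is.null(names(y))) stop("intensities must be named by m/z")
    if (any(!is.finite(y) | y < 0)) stop("intensities must be non-negative")
    mz <- sp$base_mz + 0:length(sp$carbon_sources)
    v <- stats::setNames(rep(0, length(mz)), mz)
    known <- intersect(names(y), names(v))
    extra <- setdiff(names(y), names(v))
    if (length(extra) > 0L)
      stop("intensity at m/z outside the fragment envelope of ", sp$analyte,
           " ", sp$base_mz, ": ", paste(extra, collapse = ", "))
    v[known] <- y[known]
    tot <- sum(v)
    if (tot <= 0) stop("all-zero intensities for fragment ", sp$base_mz)
    obs[[i]] <- v / tot
  }
  pools_present <- unique(unname(
    .source_pool[unlist(lapply(specs, `[[`, "carbon_sources"))]))
  identifiable <- c(co2 = "co2" %in% pools_present,
                    hcho = "hcho" %in% pools_present)
  objective <- function(par) {
    lb <- label_state(co2 = par[1L], hcho = par[2L])
    sum(vapply(seq_along(specs), function(i) {
      sum((fragment_mz(specs[[i]], lb) - obs[[i]])^2)
    }, numeric(1)))
  }
  # multistart keeps the fit off the symmetric ridge of two-pool fragments
  starts <- list(c(0.5, 0.5), c(0.25, 0.75), c(0.75, 0.25),
                 c(0.05, 0.95), c(0.95, 0.05))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, 1),
                        control = list(factr = 10, pgtol = 1e-14,
                                       maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  est <- c(co2 = best$par[1L], hcho = best$par[2L])
  est[!identifiable] <- NA_real_
  structure(list(co2 = unname(est["co2"]), hcho = unname(est["hcho"]),
                 sse = best$value, identifiable = identifiable),
            class = "rgcs_enrichment")
}

#' @export
print.rgcs_enrichment <- function(x, ...) {
  fmt <- function(v, ok) if (!ok) "undetermined" else sprintf("%.3f", v)
  cat(sprintf("<enrichment> CO2 pool: %s, HCHO pool: %s (SSE %.3g)\n",
              fmt(x$co2, x$identifiable["co2"]),
              fmt(x$hcho, x$identifiable["hcho"]), x$sse))
  invisible(x)
}

#' Shipped SIM fragment catalog
#'
#' The published quantification fragments (glycine m/z 218 and 246; serine
#' m/z 288, 302 and 390) with assumed atom retention maps: the largest
#' fragment of each analyte retains all backbone carbons, the m/z 218 / 302
#' fragments have lost the carboxyl carbon (the M-85 loss typical of silyl
#' derivatives), and m/z 288 is mapped to carboxyl+alpha. These maps are
#' editable assumptions (`inst/extdata/fragments.csv`), not measured
#' structures.
#'
#' @return Named list of [fragment_spec()]s keyed `"analyte_mz"`.
#' @export
reference_fragments <- function() {
  path <- system.file("extdata", "fragments.csv", package = "rgcskit",
                      mustWork = TRUE)
  df <- read_delim_checked(path, c("analyte", "mz", "carbon_sources"),
                           numeric_cols = "mz")
  out <- lapply(seq_len(nrow(df)), function(i) {
    srcs <- trimws(strsplit(df$carbon_sources[i], ";", fixed = TRUE)[[1L]])
    fragment_spec(df$analyte[i], df$mz[i], srcs)
  })
  names(out) <- paste0(df$analyte, "_", df$mz)
  out
}
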