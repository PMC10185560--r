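# Seeded generators for every input class the pipeline consumes.
#
# Each generator is a pure function of its arguments, seed included: it
# saves the caller's RNG state, seeds a fresh stream, and restores the state
# on exit, so the same seed always yields byte-identical output and
# generators never perturb the session RNG.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-analyte sub-stream: offsets the base seed by a hash of
# the analyte name, kept below 2^31.
substream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  (as.numeric(seed) + 1000003 * (h %% 1000)) %% 2147483647
}

#' Simulate an HPLC production time course
#'
#' Emulates the linear-rise-to-plateau shape of cell-free production curves:
#' `c(t) = min(true_rate * t, plateau) * (1 + eps)` with multiplicative
#' Gaussian noise `eps ~ N(0, noise_cv)`, truncated at zero. An optional
#' first-order decay after the plateau mimics intermediate analytes that are
#' consumed downstream (e.g. glycine during serine production).
#'
#' @param seed RNG seed (integer).
#' @param n_points Number of samples, >= 2.
#' @param true_rate Generating initial rate, uM/min.
#' @param plateau Plateau concentration, mM, >= 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise,
#'   >= 0.
#' @param sampling_interval Minutes between samples, > 0; the first sample is
#'   at t = 0.
#' @param decay_rate Optional post-plateau first-order decay, 1/min,
#'   >= 0 (0 = none).
#' @param analyte,run_id Labels for the emitted [time_course()].
#' @return A [time_course()].
#' @examples
#' tc <- gen_time_course(seed = 1, n_points = 8, true_rate = 75,
#'                       plateau = 16, noise_cv = 0.02)
#' @export
gen_time_course <- function(seed = 1L, n_points = 8L, true_rate = 75,
                            plateau = 16, noise_cv = 0.02,
                            sampling_interval = 10, decay_rate = 0,
                            analyte = "glycine", run_id = "sim") {
  stopifnot(n_points >= 2, noise_cv >= 0, plateau >= 0, decay_rate >= 0)
  if (!is.finite(sampling_interval) || sampling_interval <= 0)
    stop("`sampling_interval` must be > 0 (minutes)")
  times <- sampling_interval * (seq_len(n_points) - 1L)
  rate_mm <- true_rate / 1000
  mean_c <- pmin(rate_mm * times, plateau)
  if (decay_rate > 0 && plateau > 0 && rate_mm > 0) {
    t_pl <- plateau / rate_mm
    post <- times > t_pl
    mean_c[post] <- plateau * exp(-decay_rate * (times[post] - t_pl))
  }
  concs <- with_local_seed(substream_seed(seed, analyte), {
    mean_c * (1 + stats::rnorm(n_points, 0, noise_cv))
  })
  concs <- pmax(concs, 0)
  time_course(times, concs, analyte = analyte, run_id = run_id)
}

#' Simulate a SIM isotopologue intensity vector
#'
#' Multinomial draw of `counts_total` ions over the [fragment_mz()]
#' distribution at the given enrichment.
#'
#' @param seed RNG seed.
#' @param spec A [fragment_spec()].
#' @param labels A [label_state()].
#' @param counts_total Total ion count, > 0.
#' @return Named numeric vector of counts keyed by m/z, suitable for
#'   [enrichment_from_sim()].
#' @examples
#' gly <- fragment_spec("glycine", 246, c("carboxyl_CO2", "methylene_HCHO"))
#' gen_sim_intensities(1, gly, label_state(0.7, 0.9), 1e5)
#' @export
gen_sim_intensities <- function(seed = 1L, spec, labels, counts_total = 1e5) {
  stopifnot(inherits(spec, "rgcs_fragment"), inherits(labels, "rgcs_labels"))
  if (!is.finite(counts_total) || counts_total <= 0)
    stop("`counts_total` must be > 0")
  p <- fragment_mz(spec, labels)
  counts <- with_local_seed(substream_seed(seed, paste0(spec$analyte, spec$base_mz)), {
    as.numeric(stats::rmultinom(1, size = round(counts_total), prob = p))
  })
  stats::setNames(counts, names(p))
}

#' Simulate a perturbed reaction energy table
#'
#' Takes the shipped reference reaction table and adds independent Gaussian
#' perturbations of standard deviation `sd_kj_mol` to every known reference
#' energy, for robustness analysis of pathway profiles and flux fractions.
#' Unknown energies stay unknown.
#'
#' @param seed RNG seed.
#' @param sd_kj_mol Perturbation SD, kJ/mol, >= 0; 0 returns the reference
#'   table verbatim.
#' @return Data frame in the reaction-table dialect (see
#'   [read_reaction_table()]).
#' @examples
#' tab <- gen_energy_table(seed = 1, sd_kj_mol = 0.5)
#' @export
gen_energy_table <- function(seed = 1L, sd_kj_mol = 0) {
  stopifnot(is.finite(sd_kj_mol), sd_kj_mol >= 0)
  tab <- read_reaction_table(system.file("extdata", "reactions.csv",
                                         package = "rgcskit", mustWork = TRUE))
  if (sd_kj_mol > 0) {
    known <- !is.na(tab$ref_energy_kj_mol)
    noise <- with_local_seed(substream_seed(seed, "energy"), {
      stats::rnorm(sum(known), 0, sd_kj_mol)
    })
    tab$ref_energy_kj_mol[known] <- tab$ref_energy_kj_mol[known] + noise
    tab$source[known] <- "user"
  }
  tab
}
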