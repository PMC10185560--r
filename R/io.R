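# Table readers/writers and the consolidated report.

#' Read and validate a delimited table
#'
#' Strict reader for the package's delimited-text dialects: UTF-8, header
#' row required, comma (default) or tab separated. Missing columns, cells
#' that fail numeric conversion, and duplicate ids are rejected with the
#' offending row named; there is no silent coercion.
#'
#' @param path File path.
#' @param required_cols Character vector of required column names.
#' @param numeric_cols Columns to convert to numeric; empty strings become
#'   `NA` (explicit unknown), anything else non-numeric errors.
#' @param id_col Optional column checked for duplicates.
#' @param sep Field separator; `","` or `"\t"`.
#' @return Data frame of validated rows.
#' @export
read_delim_checked <- function(path, required_cols, numeric_cols = character(0),
                               id_col = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character", comment.char = "",
                          fileEncoding = "UTF-8")
  miss <- setdiff(required_cols, names(df))
  if (length(miss) > 0L)
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  for (col in numeric_cols) {
    raw <- df[[col]]
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(out))
    if (length(bad) > 0L)
      stop("non-numeric value in column '", col, "' of ", basename(path),
           ", data row ", bad[1L], ": '", raw[bad[1L]], "'")
    out[!nzchar(raw)] <- NA_real_
    df[[col]] <- out
  }
  if (!is.null(id_col) && anyDuplicated(df[[id_col]]))
    stop("duplicate id(s) in ", basename(path), ": ",
         paste(unique(df[[id_col]][duplicated(df[[id_col]])]), collapse = ", "))
  df
}

#' Read a reaction table
#'
#' Columns: `id`, `name`, `equation`, `ref_energy_kj_mol` (empty = unknown),
#' `ref_ph`, `ref_ionic_strength`, `source`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame.
#' @export
read_reaction_table <- function(path, sep = ",") {
  read_delim_checked(path,
                     c("id", "name", "equation", "ref_energy_kj_mol",
                       "ref_ph", "ref_ionic_strength", "source"),
                     numeric_cols = c("ref_energy_kj_mol", "ref_ph",
                                      "ref_ionic_strength"),
                     id_col = "id", sep = sep)
}

#' Read a pathway table
#'
#' Columns: `id`, `name`, `step_ids` (semicolon-separated reaction ids),
#' `description`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Data frame.
#' @export
read_pathway_table <- function(path, sep = ",") {
  read_delim_checked(path, c("id", "name", "step_ids", "description"),
                     id_col = "id", sep = sep)
}

#' Read concentration time courses
#'
#' Columns: `run_id`, `analyte`, `time_min`, `conc_mM`. Each
#' (run_id, analyte) pair becomes one [time_course()].
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Named list of [time_course()]s keyed `"run_id/analyte"`.
#' @export
read_time_course_table <- function(path, sep = ",") {
  df <- read_delim_checked(path, c("run_id", "analyte", "time_min", "conc_mM"),
                           numeric_cols = c("time_min", "conc_mM"), sep = sep)
  if (anyNA(df$time_min) || anyNA(df$conc_mM))
    stop("empty time/concentration cells in ", basename(path))
  keys <- paste(df$run_id, df$analyte, sep = "/")
  out <- lapply(split(df, keys), function(g) {
    g <- g[order(g$time_min), ]
    time_course(g$time_min, g$conc_mM, analyte = g$analyte[1L],
                run_id = g$run_id[1L])
  })
  out
}

#' Write time courses to the delimited dialect
#'
#' @param tcs A [time_course()] or list of them.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_time_course_table <- function(tcs, path, sep = ",") {
  if (inherits(tcs, "rgcs_time_course")) tcs <- list(tcs)
  rows <- do.call(rbind, lapply(tcs, function(tc) {
    data.frame(run_id = tc$run_id, analyte = tc$analyte,
               time_min = tc$times, conc_mM = tc$concs)
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a SIM intensity table
#'
#' Columns: `analyte`, `mz`, `intensity`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Named list (by analyte) of named count vectors keyed by m/z.
#' @export
read_sim_table <- function(path, sep = ",") {
  df <- read_delim_checked(path, c("analyte", "mz", "intensity"),
                           numeric_cols = c("mz", "intensity"), sep = sep)
  lapply(split(df, df$analyte),
         function(g) stats::setNames(g$intensity, g$mz))
}

#' Read an evaluation condition from a key-value file
#'
#' Plain `key = value` lines (also accepts `key: value`); keys `ph`,
#' `ionic_strength`, `temperature`, `default_conc`, all optional with
#' [condition()] defaults.
#'
#' @param path File path.
#' @return A [condition()].
#' @export
read_condition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[=:]")[[1L]]
    if (length(parts) != 2L) stop("cannot parse condition line: ", ln)
    key <- trimws(parts[1L]); val <- suppressWarnings(as.numeric(trimws(parts[2L])))
    if (is.na(val)) stop("non-numeric condition value in line: ", ln)
    kv[[key]] <- val
  }
  allowed <- c("ph", "ionic_strength", "temperature", "default_conc")
  bad <- setdiff(names(kv), allowed)
  if (length(bad) > 0L) stop("unknown condition key(s): ", paste(bad, collapse = ", "))
  do.call(condition, kv)
}

#' Consolidated analysis report
#'
#' Recomputes every headline quantity of the cascade analysis from the
#' shipped reference inputs at the given condition: the Hess-law reductant
#' substitution, flux-force fractions, rate fits and fold changes, all
#' titer/yield pairings, capture bookkeeping, and labeling shifts. Each row
#' carries the unrounded value, the rounded report value, units, and
#' provenance (`"reference"` input vs `"computed"`).
#'
#' @param condition Evaluation [condition()]; default the physiological
#'   profiling convention.
#' @param feasibility_threshold Single-step barrier limit for pathway
#'   classification, kJ/mol.
#' @return Object of class `rgcs_report`: a data frame (`$table`) with
#'   columns `quantity`, `value`, `report_value`, `units`, `provenance`,
#'   `note`, plus `$condition` and `$threshold`.
#' @examples
#' rep <- report_all()
#' subset(rep$table, quantity == "rgcs_dtt_overall_kj_mol")
#' @export
report_all <- function(condition = physiological_condition(),
                       feasibility_threshold = 20) {
  cat6 <- reference_catalog()
  rx <- cat6$reactions
  rows <- list()
  add <- function(quantity, value, report_value, units, provenance, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, value = value, report_value = report_value,
      units = units, provenance = provenance, note = note)
  }

  # thermodynamic coupling
  overall_nadh <- rx$rgcs_nadh$ref_energy
  lip_nadh <- rx$lip_nadh$ref_energy
  lip_dtt <- rx$lip_dtt$ref_energy
  overall_dtt <- substitute_step(overall_nadh, lip_nadh, lip_dtt)
  add("rgcs_nadh_overall_kj_mol", overall_nadh, overall_nadh, "kJ/mol", "reference")
  add("lipoamide_nadh_kj_mol", lip_nadh, lip_nadh, "kJ/mol", "reference")
  add("lipoamide_dtt_kj_mol", lip_dtt, lip_dtt, "kJ/mol", "reference")
  add("rgcs_dtt_overall_kj_mol", overall_dtt, round_half_up(overall_dtt, 1),
      "kJ/mol", "computed", "Hess-law substitution of the reductant step")

  # flux-force fractions
  fs_nadh <- flux_split(overall_nadh, condition$temperature)
  fs_dtt_step <- flux_split(lip_dtt, condition$temperature)
  add("reverse_flux_fraction_nadh_pct", 100 * fs_nadh$reverse_fraction,
      round_half_up(100 * fs_nadh$reverse_fraction, 1), "%", "computed",
      sprintf("at %.2f K", condition$temperature))
  add("forward_flux_fraction_dtt_pct", 100 * fs_dtt_step$forward_fraction,
      round_half_up(100 * fs_dtt_step$forward_fraction, 1), "%", "computed",
      sprintf("at %.2f K", condition$temperature))

  # rates: exact linear reference courses at the published rates
  tc_dtt <- time_course(c(0, 10, 20), c(0, 0.064, 0.128), run_id = "dtt")
  tc_l <- time_course(c(0, 10, 20), c(0, 0.001, 0.002), run_id = "l_nadh")
  tc_tcep <- time_course(c(0, 10, 20), c(0, 0.019, 0.038), run_id = "tcep")
  r_dtt <- fit_initial_rate(tc_dtt)$rate_um_min
  r_l <- fit_initial_rate(tc_l)$rate_um_min
  r_tcep <- fit_initial_rate(tc_tcep)$rate_um_min
  add("glycine_rate_dtt_um_min", r_dtt, round_half_up(r_dtt, 1), "uM/min", "computed")
  add("glycine_rate_l_nadh_um_min", r_l, round_half_up(r_l, 1), "uM/min", "computed")
  add("glycine_rate_tcep_um_min", r_tcep, round_half_up(r_tcep, 1), "uM/min", "computed")
  add("dtt_fold_change", fold_change(r_dtt, r_l),
      round_half_up(fold_change(r_dtt, r_l)), "fold", "computed")
  add("tcep_fold_change", fold_change(r_tcep, r_l),
      round_half_up(fold_change(r_tcep, r_l)), "fold", "computed")

  # titer/yield accounting for the four production scenarios
  gly_hcho <- yield_spec("glycine", "formaldehyde", 1)
  gly_co2 <- yield_spec("glycine", "co2", 1)
  gly_meoh <- yield_spec("glycine", "methanol", 1)
  ser_meoh <- yield_spec("serine", "methanol", 2)
  ser_co2 <- yield_spec("serine", "co2", 1)
  scenarios <- list(
    list(key = "bicarbonate", product = "glycine", titer = 15.5,
         c1 = 20, c1_spec = gly_hcho, co2 = 50),
    list(key = "air_capture", product = "glycine", titer = 17.1,
         c1 = 20, c1_spec = gly_hcho, co2 = 50),
    list(key = "methanol", product = "glycine", titer = 13.2,
         c1 = 20, c1_spec = gly_meoh, co2 = 50),
    list(key = "methanol_serine", product = "serine", titer = 7.5,
         c1 = 50, c1_spec = ser_meoh, co2 = 50))
  for (sc in scenarios) {
    y1 <- carbon_yield(sc$titer, sc$c1, sc$c1_spec)
    y2 <- carbon_yield(sc$titer, sc$co2,
                       if (sc$product == "serine") ser_co2 else gly_co2)
    gl <- mm_to_g_per_l(sc$titer, sc$product)
    add(paste0(sc$key, "_titer_mm"), sc$titer, sc$titer, "mM", "reference")
    add(paste0(sc$key, "_titer_g_l"), gl$g_per_l, gl$g_per_l_report, "g/L", "computed")
    add(paste0(sc$key, "_yield_c1_pct"), y1$percent, y1$percent_report, "%",
        "computed", paste0("on ", sc$c1_spec$substrate))
    add(paste0(sc$key, "_yield_co2_pct"), y2$percent, y2$percent_report, "%",
        "computed", "on CO2")
  }
  pyr <- mm_to_g_per_l(6.9, "pyruvate")
  add("pyruvate_titer_mm", 6.9, 6.9, "mM", "reference")
  add("pyruvate_titer_g_l", pyr$g_per_l, pyr$g_per_l_report, "g/L", "computed")

  # direct air capture
  rec <- capture_record(0.020, 1, co2_captured = 0.004, duration = 72)
  stock <- captured_concentration(rec)
  dl <- dilute(stock, 0.050)
  ph <- carbonate_ph(rec$base_molarity, stock)
  add("captured_bicarbonate_mm", 1000 * stock, round_half_up(1000 * stock),
      "mM", "computed")
  add("capture_dilution_factor", dl$factor, dl$factor, "fold", "computed")
  add("capture_solution_ph", ph, round_half_up(ph, 1), "pH", "computed",
      "closed-system speciation; differs from the reported ~8.6")

  # labeling: fully labeled pools put the whole glycine envelope at base+2
  gly246 <- fragment_spec("glycine", 246, c("carboxyl_CO2", "methylene_HCHO"))
  shift2 <- fragment_mz(gly246, label_state(1, 1))[["248"]]
  add("glycine_m2_fraction_full_label", shift2, shift2, "fraction", "computed")

  # pathway feasibility classification
  for (pid in names(cat6$pathways)) {
    prof <- profile_pathway(cat6$pathways[[pid]], cat6, condition,
                            feasibility_threshold)
    add(paste0("pathway_", pid, "_overall_kj_mol"),
        prof$overall, if (is.na(prof$overall)) NA else round_half_up(prof$overall, 1),
        "kJ/mol", "computed",
        if (is.na(prof$feasible)) "partial profile (unknown steps)"
        else if (prof$feasible) "feasible" else "infeasible")
  }

  structure(list(table = do.call(rbind, rows), condition = condition,
                 threshold = feasibility_threshold),
            class = "rgcs_report")
}

#' @export
print.rgcs_report <- function(x, ...) {
  cat(sprintf("<report> %d quantities at pH %.2f, I = %.2f M, T = %.2f K\n",
              nrow(x$table), x$condition$ph, x$condition$ionic_strength,
              x$condition$temperature))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
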