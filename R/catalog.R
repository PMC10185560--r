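# Candidate glycine-synthesis pathways and their thermodynamic profiles.

#' Ordered pathway of catalog reactions
#'
#' @param id Pathway identifier (the shipped catalog uses P1..P6).
#' @param name Human-readable name.
#' @param steps Character vector of reaction ids, in pathway order; at least
#'   one step.
#' @param description Free text.
#' @return An object of class `rgcs_pathway`.
#' @export
pathway <- function(id, name = id, steps, description = "") {
  steps <- as.character(steps)
  if (length(steps) < 1L) stop("a pathway needs at least one step")
  structure(list(id = as.character(id), name = as.character(name),
                 steps = steps, description = as.character(description)),
            class = "rgcs_pathway")
}

#' @export
print.rgcs_pathway <- function(x, ...) {
  cat(sprintf("<pathway %s> %s: %s\n", x$id, x$name,
              paste(x$steps, collapse = " -> ")))
  invisible(x)
}

#' Load a reaction/pathway catalog
#'
#' Builds a validated catalog from a reaction table and a pathway table (as
#' data frames, see [read_reaction_table()] and [read_pathway_table()] for the
#' file dialect). Every step id in every pathway must resolve to a reaction;
#' duplicate ids are rejected. Reactions whose `ref_energy_kj_mol` is empty
#' are carried as explicit unknowns, never as zeros.
#'
#' @param reactions Data frame with columns `id`, `name`, `equation`,
#'   `ref_energy_kj_mol`, `ref_ph`, `ref_ionic_strength`, `source`.
#' @param pathways Data frame with columns `id`, `name`, `step_ids`
#'   (semicolon-separated), `description`. May have zero rows.
#' @param default_conc Reference default concentration (mol/L) attached to
#'   every reaction's reference condition; the shipped catalog is stated at
#'   the 1 mM convention.
#' @return An object of class `rgcs_catalog`: list with `reactions` (named
#'   list of [reaction()]s) and `pathways` (named list of [pathway()]s).
#' @examples
#' cat6 <- reference_catalog()
#' length(cat6$pathways)  # 6
#' @export
load_catalog <- function(reactions, pathways, default_conc = 1e-3) {
  req_rx <- c("id", "name", "equation", "ref_energy_kj_mol", "ref_ph",
              "ref_ionic_strength", "source")
  miss <- setdiff(req_rx, names(reactions))
  if (length(miss) > 0L)
    stop("reaction table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction id(s): ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  rx <- vector("list", nrow(reactions))
  names(rx) <- reactions$id
  for (i in seq_len(nrow(reactions))) {
    row <- reactions[i, ]
    cond <- condition(ph = row$ref_ph, ionic_strength = row$ref_ionic_strength,
                      default_conc = default_conc)
    rx[[i]] <- reaction(id = row$id, name = row$name, equation = row$equation,
                        ref_energy = row$ref_energy_kj_mol,
                        ref_condition = cond, source = row$source)
  }
  req_pw <- c("id", "name", "step_ids", "description")
  miss <- setdiff(req_pw, names(pathways))
  if (length(miss) > 0L)
    stop("pathway table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(pathways$id))
    stop("duplicate pathway id(s): ",
         paste(unique(pathways$id[duplicated(pathways$id)]), collapse = ", "))
  pw <- vector("list", nrow(pathways))
  names(pw) <- pathways$id
  for (i in seq_len(nrow(pathways))) {
    row <- pathways[i, ]
    steps <- trimws(strsplit(row$step_ids, ";", fixed = TRUE)[[1L]])
    steps <- steps[nzchar(steps)]
    dangling <- setdiff(steps, names(rx))
    if (length(dangling) > 0L)
      stop("pathway '", row$id, "' references missing reaction(s): ",
           paste(dangling, collapse = ", "))
    pw[[i]] <- pathway(id = row$id, name = row$name, steps = steps,
                       description = row$description)
  }
  structure(list(reactions = rx, pathways = pw), class = "rgcs_catalog")
}

#' @export
print.rgcs_catalog <- function(x, ...) {
  cat(sprintf("<catalog> %d reactions, %d pathways\n",
              length(x$reactions), length(x$pathways)))
  for (p in x$pathways) print(p)
  invisible(x)
}

#' The shipped six-pathway glycine-synthesis catalog
#'
#' Loads the packaged reference tables: six candidate routes from C1
#' substrates (formate, methanol, formaldehyde, CO2) to glycine, at the
#' coarse step granularity of the published pathway map, with reference
#' transformed energies at pH 7.5, I = 0.20 M, 1 mM reactants where the
#' source prints them and explicit unknowns elsewhere.
#'
#' @return An `rgcs_catalog`.
#' @export
reference_catalog <- function() {
  load_catalog(
    read_reaction_table(system.file("extdata", "reactions.csv",
                                    package = "rgcskit", mustWork = TRUE)),
    read_pathway_table(system.file("extdata", "pathways.csv",
                                   package = "rgcskit", mustWork = TRUE)))
}

#' Thermodynamic profile of a pathway
#'
#' Evaluates each step's Delta_r G' at the given condition (reference values
#' adjusted to the condition's default concentration via
#' [adjust_concentrations()] when the condition differs from the reference;
#' identical conditions return stored values unchanged), accumulates the
#' running sum, locates the bottleneck (most positive step, earliest on
#' ties), and classifies feasibility as "no step above the threshold".
#' Steps with unknown energies yield a partial profile: their entries are
#' `NA`, `overall` is `NA`, and `feasible` is `NA` (undetermined) — unknowns
#' are never silently zero.
#'
#' @param pathway An [pathway()].
#' @param catalog An `rgcs_catalog` resolving the step ids.
#' @param condition Evaluation [condition()].
#' @param feasibility_threshold Maximum tolerable single-step barrier,
#'   kJ/mol. Default +20.
#' @return An object of class `rgcs_profile`: `step_ids`, `step_energies`,
#'   `cumulative`, `bottleneck_index`, `overall`, `feasible`, `partial`,
#'   `threshold`, `condition`.
#' @examples
#' cat6 <- reference_catalog()
#' profile_pathway(cat6$pathways$P6, cat6)
#' @export
profile_pathway <- function(pathway, catalog,
                            condition = physiological_condition(),
                            feasibility_threshold = 20) {
  stopifnot(inherits(pathway, "rgcs_pathway"), inherits(catalog, "rgcs_catalog"),
            inherits(condition, "rgcs_condition"),
            is.finite(feasibility_threshold))
  dangling <- setdiff(pathway$steps, names(catalog$reactions))
  if (length(dangling) > 0L)
    stop("pathway '", pathway$id, "' references missing reaction(s): ",
         paste(dangling, collapse = ", "))
  energies <- vapply(pathway$steps, function(sid) {
    rx <- catalog$reactions[[sid]]
    if (is.na(rx$ref_energy)) return(NA_real_)
    ref <- rx$ref_condition
    if (isTRUE(all.equal(ref$default_conc, condition$default_conc)) &&
        isTRUE(all.equal(ref$temperature, condition$temperature))) {
      rx$ref_energy
    } else {
      adjust_concentrations(rx, condition)
    }
  }, numeric(1))
  partial <- anyNA(energies)
  cumulative <- cumsum(energies)          # NA propagates past unknown steps
  if (all(is.na(energies))) {
    bn <- NA_integer_
  } else {
    bn <- unname(which.max(energies))     # drops NA, earliest max wins
  }
  overall <- if (partial) NA_real_ else sum(energies)
  feasible <- if (partial) NA else max(energies) <= feasibility_threshold
  structure(list(pathway_id = pathway$id, step_ids = pathway$steps,
                 step_energies = unname(energies), cumulative = unname(cumulative),
                 bottleneck_index = bn, overall = overall, feasible = feasible,
                 partial = partial, threshold = feasibility_threshold,
                 condition = condition),
            class = "rgcs_profile")
}

#' @export
print.rgcs_profile <- function(x, ...) {
  cat(sprintf("<profile %s> %s (threshold %+.1f kJ/mol)\n", x$pathway_id,
              if (is.na(x$feasible)) "feasibility undetermined (partial profile)"
              else if (x$feasible) "feasible" else "infeasible",
              x$threshold))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  if (!is.na(x$overall))
    cat(sprintf("overall: %.1f kJ/mol; bottleneck at step %d (%s)\n",
                x$overall, x$bottleneck_index, x$step_ids[x$bottleneck_index]))
  invisible(x)
}

#' @export
as.data.frame.rgcs_profile <- function(x, ...) {
  data.frame(step = seq_along(x$step_ids), reaction = x$step_ids,
             delta_g_kj_mol = x$step_energies,
             cumulative_kj_mol = x$cumulative)
}
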