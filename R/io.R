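# File formats: JSON clone configurations and regimen plans, CSV viability
# tables and regimen traces. All numeric round trips are exact to 12
# significant digits (the JSON writer's precision).

.SCHEMA_VERSION <- 1L

.config_fail <- function(location, reason) {
  .stop_samclone(sprintf("%s: %s", location, reason), "samclone_schema")
}

#' Load a clone configuration from JSON
#'
#' The document carries a `schema_version`, a `clones` array (each element:
#' `id`, `fraction`, `x`, `y`, `z`, optional `d_i`, `w_i` and a
#' `dose_params` map of dose label to `{x, z}`), and an optional
#' `default_drug` object `{d, alpha}`. All range and sum invariants are
#' enforced on load with the offending field named in the error.
#'
#' @param path Path to the JSON file.
#' @param normalise Rescale fractions to sum to 1 instead of erroring.
#' @return List with `population` (a [clone_population()]) and `drug`
#'   (a [drug_spec()], or `NULL` when the file has no `default_drug`).
#' @export
load_clone_config <- function(path, normalise = FALSE) {
  if (!file.exists(path)) {
    .stop_samclone(sprintf("file not found: %s", path), "samclone_schema")
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc[["clones"]]) || length(doc[["clones"]]) == 0) {
    .config_fail("$.clones", "missing or empty clones array")
  }
  clones <- lapply(seq_along(doc[["clones"]]), function(i) {
    cj <- doc[["clones"]][[i]]
    loc <- sprintf("$.clones[%d]", i)
    for (field in c("id", "fraction", "x", "y", "z")) {
      if (is.null(cj[[field]])) {
        .config_fail(paste0(loc, ".", field), "required field missing")
      }
    }
    for (field in c("fraction", "x", "y", "z", "d_i", "w_i")) {
      val <- cj[[field]]
      if (!is.null(val) && (!is.numeric(val) || val < -.TOL_VALID ||
                            val > 1 + .TOL_VALID)) {
        .config_fail(paste0(loc, ".", field), "must be a number in [0, 1]")
      }
    }
    dose_params <- NULL
    if (!is.null(cj[["dose_params"]])) {
      dose_params <- lapply(cj[["dose_params"]], function(dp) {
        list(x = dp[["x"]], z = dp[["z"]])
      })
    }
    clone(cj[["id"]], cj[["fraction"]],
          clone_params(cj[["x"]], cj[["y"]], cj[["z"]]),
          drug_efficacy_override = cj[["d_i"]], priority_weight = cj[["w_i"]],
          dose_params = dose_params)
  })
  pop <- tryCatch(
    clone_population(clones, normalise = normalise),
    samclone_error = function(e) .config_fail("$.clones", conditionMessage(e))
  )
  drug <- NULL
  if (!is.null(doc[["default_drug"]])) {
    dd <- doc[["default_drug"]]
    if (is.null(dd[["d"]])) .config_fail("$.default_drug.d", "required field missing")
    drug <- drug_spec(dd[["d"]], if (is.null(dd[["alpha"]])) 1 else dd[["alpha"]])
  }
  list(population = pop, drug = drug)
}

#' Write a clone configuration to JSON
#'
#' @param pop A [clone_population()].
#' @param path Output path.
#' @param drug Optional [drug_spec()] stored as `default_drug`.
#' @return `path`, invisibly.
#' @export
save_clone_config <- function(pop, path, drug = NULL) {
  clones <- lapply(pop$clones, function(cl) {
    out <- list(id = cl$id, fraction = cl$fraction,
                x = cl$params$x, y = cl$params$y, z = cl$params$z)
    if (!is.null(cl$drug_efficacy_override)) out$d_i <- cl$drug_efficacy_override
    if (!is.null(cl$priority_weight)) out$w_i <- cl$priority_weight
    if (!is.null(cl$dose_params)) out$dose_params <- cl$dose_params
    out
  })
  doc <- list(schema_version = .SCHEMA_VERSION, clones = clones)
  if (!is.null(drug)) doc[["default_drug"]] <- list(d = drug$d, alpha = drug$alpha)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE)
  invisible(path)
}

#' Load a regimen plan from JSON
#'
#' The document holds an ordered `cycles` array; each cycle has `drug_on`,
#' optional `d` (default 0), `alpha` (default 1) and `dose_label`.
#'
#' @param path Path to the JSON file.
#' @param population Optional [clone_population()]; when given, every
#'   referenced `dose_label` is checked to resolve against every clone's
#'   dose-parameter map.
#' @return List of [cycle_plan()] objects.
#' @export
load_regimen <- function(path, population = NULL) {
  if (!file.exists(path)) {
    .stop_samclone(sprintf("file not found: %s", path), "samclone_schema")
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc[["cycles"]]) || length(doc[["cycles"]]) == 0) {
    .config_fail("$.cycles", "missing or empty cycles array")
  }
  plans <- lapply(seq_along(doc[["cycles"]]), function(i) {
    cy <- doc[["cycles"]][[i]]
    loc <- sprintf("$.cycles[%d]", i)
    if (is.null(cy[["drug_on"]])) .config_fail(paste0(loc, ".drug_on"),
                                          "required field missing")
    plan <- tryCatch(
      cycle_plan(drug_on = cy[["drug_on"]],
                 d = if (is.null(cy[["d"]])) 0 else cy[["d"]],
                 alpha = if (is.null(cy[["alpha"]])) 1 else cy[["alpha"]],
                 dose_label = cy[["dose_label"]]),
      samclone_error = function(e) .config_fail(loc, conditionMessage(e))
    )
    if (!is.null(plan$dose_label) && !is.null(population)) {
      for (cl in population$clones) {
        if (is.null(cl$dose_params[[plan$dose_label]])) {
          .config_fail(paste0(loc, ".dose_label"),
                       sprintf("label '%s' not defined for clone '%s'",
                               plan$dose_label, cl$id))
        }
      }
    }
    plan
  })
  plans
}

#' Read a viability table from CSV
#'
#' Expected columns: `concentration_uM`, `condition`, optional
#' `samhd1_relative`, `replicate`, `viability`. Viability may be on the
#' percent scale (`percent = TRUE`); it is normalised to a fraction.
#'
#' @param path CSV path (comma separator, header row, '.' decimal).
#' @param percent Viability column is in percent.
#' @return Validated viability data frame.
#' @export
read_viability_table <- function(path, percent = FALSE) {
  if (!file.exists(path)) {
    .stop_samclone(sprintf("file not found: %s", path), "samclone_schema")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (percent && "viability" %in% names(tab)) {
    tab$viability <- tab$viability / 100
  }
  .check_viability_table(tab)
}

#' Write a regimen trace as tidy CSV
#'
#' One row per cycle per clone with the columns documented in
#' [simulate_regimen()].
#'
#' @param trace A `regimen_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regimen_trace <- function(trace, path) {
  utils::write.csv(trace$table, path, row.names = FALSE)
  invisible(path)
}
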