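#' A single AML clone within a population
#'
#' @param id Unique clone label.
#' @param fraction Fraction of the total cell population in \eqn{[0, 1]}.
#' @param params [clone_params()] for the clone (x, y, z).
#' @param drug_efficacy_override Optional per-clone inhibitor efficacy d_i
#'   taking precedence over a cycle plan's `d` (e.g. efflux-pump expression
#'   differences between clones).
#' @param priority_weight Optional clinician-assigned weight w_i for the
#'   weighted objective (see [weighted_efficacy()]).
#' @param dose_params Optional named list mapping a dose label to a
#'   `list(x =, z =)` pair, modelling how the ara-C dose modulates both the
#'   intrinsic efficacy x and the SAMHD1 interference z for this clone.
#' @return An object of class `samclone_clone`.
#' @export
clone <- function(id, fraction, params, drug_efficacy_override = NULL,
                  priority_weight = NULL, dose_params = NULL) {
  fraction <- .check_fraction(fraction, "fraction", 1L)
  params <- .as_clone_params(params)
  if (!is.null(drug_efficacy_override)) {
    drug_efficacy_override <- .check_fraction(drug_efficacy_override,
                                              "drug_efficacy_override", 1L)
  }
  if (!is.null(priority_weight)) {
    priority_weight <- .check_fraction(priority_weight, "priority_weight", 1L)
  }
  if (!is.null(dose_params)) {
    if (is.null(names(dose_params)) || any(names(dose_params) == "")) {
      .stop_samclone("dose_params must be a named list of list(x =, z =)",
                     "samclone_invalid_parameter")
    }
    dose_params <- lapply(dose_params, function(dp) {
      list(x = .check_fraction(dp$x, "dose x", 1L),
           z = .check_fraction(dp$z, "dose z", 1L))
    })
  }
  structure(list(id = as.character(id), fraction = fraction, params = params,
                 drug_efficacy_override = drug_efficacy_override,
                 priority_weight = priority_weight,
                 dose_params = dose_params),
            class = "samclone_clone")
}

#' An oligoclonal AML population
#'
#' A set of named clones with fractions summing to 1. If any clone carries a
#' priority weight, all must, and the weights must also sum to 1.
#'
#' @param ... [clone()] objects, or a single list of them.
#' @param normalise If `TRUE`, fractions are rescaled to sum to 1 instead of
#'   erroring on a fraction-sum violation.
#' @return An object of class `clone_population`.
#' @examples
#' pop <- clone_population(
#'   clone("resistant", 0.5, clone_params(0.8, 0.3, 0.7)),
#'   clone("sensitive", 0.5, clone_params(0.8, 0.1, 0.2))
#' )
#' total_efficacy(pop, cycle_plan(drug_on = FALSE))
#' @export
clone_population <- function(..., normalise = FALSE) {
  clones <- list(...)
  if (length(clones) == 1 && !inherits(clones[[1]], "samclone_clone")) {
    clones <- clones[[1]]
  }
  if (length(clones) == 0) {
    .stop_samclone("a population needs at least one clone",
                   "samclone_invalid_parameter")
  }
  if (!all(vapply(clones, inherits, logical(1), "samclone_clone"))) {
    .stop_samclone("all elements must be clone() objects",
                   "samclone_invalid_parameter")
  }
  ids <- vapply(clones, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    .stop_samclone(sprintf("duplicate clone ids: %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                   "samclone_duplicate_ids")
  }
  fr <- vapply(clones, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > .TOL_VALID) {
    if (normalise) {
      if (sum(fr) <= 0) {
        .stop_samclone("cannot normalise fractions summing to 0",
                       "samclone_fraction_sum")
      }
      fr <- fr / sum(fr)
      for (i in seq_along(clones)) clones[[i]]$fraction <- fr[i]
    } else {
      .stop_samclone(
        sprintf("clone fractions sum to %.6g, not 1 (set normalise = TRUE to rescale)",
                sum(fr)),
        "samclone_fraction_sum")
    }
  }
  w <- lapply(clones, `[[`, "priority_weight")
  has_w <- !vapply(w, is.null, logical(1))
  if (any(has_w)) {
    if (!all(has_w)) {
      .stop_samclone("priority weights must be set for all clones or none",
                     "samclone_invalid_parameter")
    }
    if (abs(sum(unlist(w)) - 1) > .TOL_VALID) {
      .stop_samclone("priority weights must sum to 1",
                     "samclone_invalid_parameter")
    }
  }
  structure(list(clones = clones), class = "clone_population")
}

#' @export
print.clone_population <- function(x, ...) {
  cat(sprintf("<clone_population> %d clone(s)\n", length(x$clones)))
  for (cl in x$clones) {
    cat(sprintf("  %s: f = %.4f, x = %g, y = %g, z = %g%s\n",
                cl$id, cl$fraction, cl$params$x, cl$params$y, cl$params$z,
                if (!is.null(cl$drug_efficacy_override))
                  sprintf(", d_i = %g", cl$drug_efficacy_override) else ""))
  }
  invisible(x)
}

#' @export
length.clone_population <- function(x) length(x$clones)

# Matrix view of the population: one row per clone.
.pop_matrix <- function(pop) {
  data.frame(
    id = vapply(pop$clones, `[[`, character(1), "id"),
    fraction = vapply(pop$clones, `[[`, numeric(1), "fraction"),
    x = vapply(pop$clones, function(cl) cl$params$x, numeric(1)),
    y = vapply(pop$clones, function(cl) cl$params$y, numeric(1)),
    z = vapply(pop$clones, function(cl) cl$params$z, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Replace fractions, preserving everything else.
.set_fractions <- function(pop, fractions) {
  for (i in seq_along(pop$clones)) pop$clones[[i]]$fraction <- fractions[i]
  pop
}

#' One cycle of a treatment regimen
#'
#' A cycle is always an ara-C cycle; the plan states whether the SAMHD1
#' inhibitor is co-administered and with what efficacy and specificity, and
#' optionally selects a per-clone (x, z) pair through a dose label (ara-C
#' dose modulates both its own efficacy and the degree of SAMHD1
#' interference).
#'
#' @param drug_on Logical: is the SAMHD1 inhibitor given this cycle?
#' @param d Inhibitor efficacy (ara-CTPase side) used when `drug_on`;
#'   overridden per clone by `drug_efficacy_override`.
#' @param alpha Inhibitor specificity ratio.
#' @param dose_label Optional label resolved against each clone's
#'   `dose_params` map.
#' @return An object of class `cycle_plan`.
#' @export
cycle_plan <- function(drug_on = FALSE, d = 0, alpha = 1, dose_label = NULL) {
  d <- .check_fraction(d, "d", 1L)
  alpha <- .check_fraction(alpha, "alpha", 1L)
  structure(list(drug_on = isTRUE(drug_on), d = d, alpha = alpha,
                 dose_label = dose_label),
            class = "cycle_plan")
}

# Per-clone efficacies for one cycle, honouring dose labels and per-clone
# drug-efficacy overrides.
.clone_efficacies <- function(pop, plan) {
  vapply(pop$clones, function(cl) {
    x <- cl$params$x
    z <- cl$params$z
    if (!is.null(plan$dose_label)) {
      dp <- cl$dose_params[[plan$dose_label]]
      if (is.null(dp)) {
        .stop_samclone(
          sprintf("clone '%s' has no dose parameters for label '%s'",
                  cl$id, plan$dose_label),
          "samclone_schema")
      }
      x <- dp$x
      z <- dp$z
    }
    d <- if (!plan$drug_on) 0
         else if (!is.null(cl$drug_efficacy_override)) cl$drug_efficacy_override
         else plan$d
    .efficacy(x, cl$params$y, z, d, plan$alpha)
  }, numeric(1))
}
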