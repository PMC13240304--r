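# Oligoclonal efficacy aggregation, fraction updating, regimen simulation,
# minimum-cycles analysis, greedy next-cycle choice, and d-fitting from
# observed fraction ratios.

#' Total efficacy of one cycle on an oligoclonal population
#'
#' By the law of total probability over clones, the population-level
#' efficacy is the fraction-weighted mean of the per-clone efficacies:
#' \deqn{e_{total} = \sum_i f_i e_i.}
#'
#' @param pop A [clone_population()].
#' @param plan A [cycle_plan()]; defaults to ara-C alone.
#' @return Total efficacy in \eqn{[\min_i e_i, \max_i e_i]}.
#' @export
total_efficacy <- function(pop, plan = cycle_plan()) {
  e <- .clone_efficacies(pop, plan)
  f <- vapply(pop$clones, `[[`, numeric(1), "fraction")
  sum(f * e)
}

#' Priority-weighted efficacy
#'
#' Clinicians may prioritise certain clones (e.g. a leukaemic-stem-cell
#' clone) by weights w_i summing to 1; the objective becomes
#' \eqn{\sum_i w_i e_i} instead of the fraction-weighted total.
#'
#' @inheritParams total_efficacy
#' @return Weighted efficacy.
#' @export
weighted_efficacy <- function(pop, plan = cycle_plan()) {
  w <- lapply(pop$clones, `[[`, "priority_weight")
  if (any(vapply(w, is.null, logical(1)))) {
    .stop_samclone("all clones need a priority_weight for weighted_efficacy()",
                   "samclone_missing_weights")
  }
  e <- .clone_efficacies(pop, plan)
  sum(unlist(w) * e)
}

#' Update clonal fractions after one treatment cycle
#'
#' Treatment selection: a clone hit with efficacy e_i retains a fraction
#' (1 - e_i) of its cells, so its updated share of the surviving population
#' is \deqn{f_i' = \frac{f_i (1 - e_i)}{1 - e_{total}}.}
#' Clones with e_i above the population total shrink; those below grow.
#'
#' @param pop A [clone_population()].
#' @param efficacies Per-clone efficacies, one per clone in population order.
#' @return The population with updated fractions.
#' @export
update_fractions <- function(pop, efficacies) {
  efficacies <- .check_fraction(efficacies, "efficacies", length(pop$clones))
  f <- vapply(pop$clones, `[[`, numeric(1), "fraction")
  e_total <- sum(f * efficacies)
  if (1 - e_total <= .TOL_EQ) {
    .stop_samclone("population eradicated (e_total = 1): fractions undefined",
                   "samclone_eradication")
  }
  .set_fractions(pop, f * (1 - efficacies) / (1 - e_total))
}

#' Simulate a multi-cycle treatment regimen
#'
#' Iterates per-cycle efficacy computation and fraction updating over a
#' sequence of cycle plans, tracking the remaining AML burden — the
#' surviving population relative to the untreated expectation, i.e. the
#' running product of per-cycle survival \eqn{\prod_k (1 - e_{total,k})}.
#' If a cycle eradicates the population (e_total = 1 within tolerance) the
#' trace records burden 0 for that cycle and stops.
#'
#' @param pop A [clone_population()].
#' @param plans A list of [cycle_plan()] objects (or a single plan, recycled
#'   via `n_cycles`).
#' @param n_cycles If `plans` is a single plan, repeat it this many times.
#' @return An object of class `regimen_trace`: list with
#'   \describe{
#'     \item{table}{tidy data frame, one row per cycle x clone: `cycle`,
#'       `clone_id`, `fraction_before`, `efficacy`, `fraction_after`,
#'       `e_total`, `burden`.}
#'     \item{e_total}{per-cycle total efficacies.}
#'     \item{burden}{per-cycle cumulative remaining burden.}
#'     \item{final_population}{the population after the last completed
#'       cycle (`NULL` if eradicated).}
#'     \item{eradicated}{logical.}
#'   }
#' @export
simulate_regimen <- function(pop, plans, n_cycles = NULL) {
  if (inherits(plans, "cycle_plan")) {
    plans <- rep(list(plans), if (is.null(n_cycles)) 1L else n_cycles)
  }
  if (length(plans) == 0) {
    .stop_samclone("plans must be non-empty", "samclone_invalid_parameter")
  }
  rows <- vector("list", length(plans))
  e_tot <- numeric(0)
  burden <- numeric(0)
  b <- 1
  eradicated <- FALSE
  for (k in seq_along(plans)) {
    plan <- plans[[k]]
    e <- .clone_efficacies(pop, plan)
    f_before <- vapply(pop$clones, `[[`, numeric(1), "fraction")
    et <- sum(f_before * e)
    b <- b * (1 - et)
    if (1 - et <= .TOL_EQ) {
      eradicated <- TRUE
      b <- 0
      f_after <- rep(NA_real_, length(e))
    } else {
      pop <- .set_fractions(pop, f_before * (1 - e) / (1 - et))
      f_after <- vapply(pop$clones, `[[`, numeric(1), "fraction")
    }
    rows[[k]] <- data.frame(
      cycle = k,
      clone_id = vapply(pop$clones, `[[`, character(1), "id"),
      fraction_before = f_before,
      efficacy = e,
      fraction_after = f_after,
      e_total = et,
      burden = b,
      stringsAsFactors = FALSE
    )
    e_tot <- c(e_tot, et)
    burden <- c(burden, b)
    if (eradicated) break
  }
  structure(list(
    table = do.call(rbind, rows[seq_along(e_tot)]),
    e_total = e_tot,
    burden = burden,
    final_population = if (eradicated) NULL else pop,
    eradicated = eradicated
  ), class = "regimen_trace")
}

#' @export
print.regimen_trace <- function(x, ...) {
  cat(sprintf("<regimen_trace> %d cycle(s); final burden %.6g%s\n",
              length(x$e_total), x$burden[length(x$burden)],
              if (x$eradicated) " (eradicated)" else ""))
  invisible(x)
}

#' Drug-free cycles needed before adding the inhibitor pays off
#'
#' Under ara-C-only treatment, clones that the inhibitor would help (low y,
#' high z) are hit least and therefore expand, so the inhibitor's value
#' grows over cycles. This returns the smallest k >= 0 such that, after k
#' drug-free cycles of fraction updating, the (k+1)-th cycle's total
#' efficacy with the drug strictly exceeds that without it (a myopic,
#' per-cycle comparison), or `NA` if no such k <= `max_cycles` exists.
#'
#' @param pop A [clone_population()].
#' @param d Inhibitor efficacy to evaluate.
#' @param alpha Inhibitor specificity ratio.
#' @param max_cycles Search horizon.
#' @return Integer count of drug-free cycles, or `NA_integer_`.
#' @export
min_cycles_until_drug_beneficial <- function(pop, d, alpha = 1,
                                             max_cycles = 50L) {
  if (max_cycles < 1) {
    .stop_samclone("max_cycles must be >= 1", "samclone_invalid_parameter")
  }
  plan_off <- cycle_plan(drug_on = FALSE)
  plan_on <- cycle_plan(drug_on = TRUE, d = d, alpha = alpha)
  for (k in 0:max_cycles) {
    e_off <- .clone_efficacies(pop, plan_off)
    f <- vapply(pop$clones, `[[`, numeric(1), "fraction")
    et_off <- sum(f * e_off)
    et_on <- total_efficacy(pop, plan_on)
    if (et_on > et_off + .TOL_EQ) return(k)
    if (1 - et_off <= .TOL_EQ) {
      .stop_samclone(
        sprintf("population eradicated after %d drug-free cycle(s)", k + 1),
        "samclone_eradication")
    }
    pop <- .set_fractions(pop, f * (1 - e_off) / (1 - et_off))
  }
  NA_integer_
}

#' Pick the best plan for the next cycle
#'
#' Greedy single-cycle optimisation: evaluates each candidate plan on the
#' current fractions and returns the one maximising the chosen objective.
#' Ties are broken by earliest candidate order.
#'
#' @param pop A [clone_population()].
#' @param candidates A list of [cycle_plan()] objects.
#' @param objective `"total"` ([total_efficacy()]) or `"weighted"`
#'   ([weighted_efficacy()]).
#' @return List with `plan` (the winning candidate), `score` and `index`.
#' @export
optimize_next_cycle <- function(pop, candidates, objective = c("total",
                                                               "weighted")) {
  objective <- match.arg(objective)
  if (length(candidates) == 0) {
    .stop_samclone("candidates must be non-empty",
                   "samclone_invalid_parameter")
  }
  obj <- if (objective == "total") total_efficacy else weighted_efficacy
  scores <- vapply(candidates, function(pl) obj(pop, pl), numeric(1))
  i <- which.max(scores) # first maximum: earliest-candidate tie-break
  list(plan = candidates[[i]], score = scores[i], index = i)
}

#' Fit the inhibitor efficacy d from observed fraction shifts
#'
#' After a treated cycle, the observed ratios f_i'/f_i identify the drug
#' efficacy through the fraction-update law
#' \eqn{f_i'/f_i = (1 - e_i(d)) / (1 - e_{total}(d))}. This fits d by least
#' squares on those ratios: a dense grid over \eqn{[0, 1]} (step 1e-3)
#' followed by local bounded refinement with [stats::optimize()].
#'
#' @param pre A [clone_population()] with pre-treatment fractions and known
#'   clone parameters (>= 2 clones).
#' @param post_fractions Observed post-treatment fractions, summing to 1,
#'   in population clone order.
#' @param alpha Inhibitor specificity ratio used during the cycle.
#' @return List with `d` (the estimate), `residual` (sum of squared ratio
#'   residuals at the optimum) and `identifiable` (logical; `FALSE`, with a
#'   warning, when the residual profile is flat, e.g. identical clones).
#' @export
fit_drug_efficacy <- function(pre, post_fractions, alpha = 1) {
  if (length(pre$clones) < 2) {
    .stop_samclone("need >= 2 clones to identify d from fraction ratios",
                   "samclone_invalid_parameter")
  }
  post_fractions <- .check_fraction(post_fractions, "post_fractions",
                                    length(pre$clones))
  if (abs(sum(post_fractions) - 1) > .TOL_VALID) {
    .stop_samclone("post_fractions must sum to 1", "samclone_fraction_sum")
  }
  f <- vapply(pre$clones, `[[`, numeric(1), "fraction")
  if (any(f <= 0)) {
    .stop_samclone("all pre-treatment fractions must be positive",
                   "samclone_invalid_parameter")
  }
  obs_ratio <- post_fractions / f
  loss <- function(d) {
    plan <- cycle_plan(drug_on = TRUE, d = d, alpha = alpha)
    e <- .clone_efficacies(pre, plan)
    et <- sum(f * e)
    if (1 - et <= .TOL_EQ) return(Inf)
    sum((obs_ratio - (1 - e) / (1 - et))^2)
  }
  grid <- seq(0, 1, by = 1e-3)
  vals <- vapply(grid, loss, numeric(1))
  finite <- is.finite(vals)
  if (!any(finite)) {
    .stop_samclone("no admissible d: every candidate eradicates the population",
                   "samclone_eradication")
  }
  if (max(vals[finite]) - min(vals[finite]) < .TOL_EQ) {
    .warn_samclone("drug efficacy not identifiable: residual profile is flat",
                   "samclone_non_identifiable")
    return(list(d = NA_real_, residual = min(vals[finite]),
                identifiable = FALSE))
  }
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(loss, lower = lo, upper = hi, tol = 1e-10)
  # keep the grid point if refinement did not improve on it
  if (vals[i] < opt$objective) {
    opt <- list(minimum = grid[i], objective = vals[i])
  }
  list(d = opt$minimum, residual = opt$objective, identifiable = TRUE)
}
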