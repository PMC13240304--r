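# Seeded synthetic-data generators: viability tables with CV-scaled noise,
# stochastic clonal trajectories, and the worked-example populations used
# throughout the documentation and tests.

#' Generate a synthetic viability table
#'
#' Emulates a Vpx-titration viability assay: for each ara-C concentration,
#' SAMHD1-null conditions (Vpx-loaded VLPs) have model viability
#' `1 - x(c)`, endogenous-SAMHD1 controls have `1 - e(x(c), y, z(c))`.
#' Each replicate is perturbed by multiplicative Gaussian noise with the
#' given coefficient of variation (sigma = cv * v) and truncated to
#' \eqn{[0, 1]}. The default cv of 0.094 matches the replicate variability
#' typical of such assays.
#'
#' @param concentrations Increasing ara-C concentrations in uM; include 0
#'   so that y can be estimated from the table.
#' @param x,z True parameter profiles, one value per concentration (x must
#'   be 0 where concentration is 0).
#' @param y True endogenous SAMHD1 suppressor efficacy.
#' @param null_conditions,control_conditions Condition labels for the
#'   SAMHD1-null and endogenous-SAMHD1 series.
#' @param replicates Replicates per concentration x condition.
#' @param cv Relative noise level; 0 gives exact model viabilities.
#' @param seed Integer seed (mandatory); the caller's RNG state is
#'   preserved.
#' @return A viability data frame (see [read_viability_table()] for the
#'   column contract).
#' @export
gen_viability_table <- function(concentrations, x, z, y = 0.0982,
                                null_conditions = "VPX:100",
                                control_conditions = c("NO_VLP",
                                                       "EMPTY_VLP:100"),
                                replicates = 3, cv = 0.094, seed) {
  if (missing(seed)) {
    .stop_samclone("seed is mandatory for fixture generation",
                   "samclone_invalid_parameter")
  }
  if (length(x) != length(concentrations) ||
      length(z) != length(concentrations)) {
    .stop_samclone("x and z must have one value per concentration",
                   "samclone_invalid_parameter")
  }
  grid <- expand.grid(
    concentration_uM = concentrations,
    condition = c(null_conditions, control_conditions),
    replicate = seq_len(replicates),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  idx <- match(grid$concentration_uM, concentrations)
  is_null <- grid$condition %in% null_conditions
  v_model <- ifelse(is_null,
                    1 - x[idx],
                    1 - .efficacy(x[idx], y, z[idx]))
  v_obs <- .with_seed(seed, {
    v_model * (1 + cv * stats::rnorm(length(v_model)))
  })
  grid$samhd1_relative <- ifelse(is_null, 0.006, 1.0)
  grid$viability <- pmin(pmax(v_obs, 0), 1)
  grid[, c("concentration_uM", "condition", "samhd1_relative", "replicate",
           "viability")]
}

# Integer allocation of K cells to fractions, exact total (largest
# remainder).
.allocate_counts <- function(K, fractions) {
  raw <- K * fractions
  counts <- floor(raw)
  short <- K - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  counts
}

#' Simulate stochastic clonal trajectories under a regimen
#'
#' Finite-population counterpart of [simulate_regimen()]: starting from K
#' cells allocated to clones by their fractions, each cycle draws per-clone
#' survivor counts binomially with survival probability `1 - e_i` and
#' re-measures the observed fractions as counts / total. As K grows the
#' observed fractions converge to the deterministic fraction-update law.
#'
#' @param pop A [clone_population()].
#' @param plans A list of [cycle_plan()] objects (or one plan).
#' @param K Initial cell count (>= 1).
#' @param seed Integer seed (mandatory).
#' @return Data frame, one row per cycle per clone: `cycle`, `clone_id`,
#'   `cells_before`, `cells_after`, `fraction_observed`. A total-extinction
#'   cycle ends the trajectory with `fraction_observed = NA` and attribute
#'   `extinct = TRUE`.
#' @export
gen_clone_trajectory <- function(pop, plans, K, seed) {
  if (missing(seed)) {
    .stop_samclone("seed is mandatory for fixture generation",
                   "samclone_invalid_parameter")
  }
  if (K < 1) .stop_samclone("K must be >= 1", "samclone_invalid_parameter")
  if (inherits(plans, "cycle_plan")) plans <- list(plans)
  ids <- vapply(pop$clones, `[[`, character(1), "id")
  counts <- .allocate_counts(K, vapply(pop$clones, `[[`, numeric(1),
                                       "fraction"))
  extinct <- FALSE
  rows <- .with_seed(seed, {
    out <- vector("list", length(plans))
    for (k in seq_along(plans)) {
      e <- .clone_efficacies(pop, plans[[k]])
      survivors <- stats::rbinom(length(counts), counts, 1 - e)
      total <- sum(survivors)
      frac <- if (total > 0) survivors / total else rep(NA_real_,
                                                        length(survivors))
      out[[k]] <- data.frame(cycle = k, clone_id = ids,
                             cells_before = counts, cells_after = survivors,
                             fraction_observed = frac,
                             stringsAsFactors = FALSE)
      if (total == 0) {
        extinct <- TRUE
        out <- out[seq_len(k)]
        break
      }
      counts <- survivors
      # observed fractions drive the next cycle's efficacies only through
      # per-clone parameters, which are fixed; counts carry the state
    }
    do.call(rbind, out)
  })
  attr(rows, "extinct") <- extinct
  rows
}

#' Worked-example clone populations
#'
#' Ready-made configurations used in the documentation and tests:
#' \describe{
#'   \item{monoclonal_high_samhd1}{one clone, x = 0.8, y = 0.1, z = 0.7 —
#'     strong ara-C, weak suppressor, strong interference; inhibitor always
#'     beneficial (base efficacy 0.316).}
#'   \item{monoclonal_conditional}{one clone, x = 0.7, y = 0.4, z = 0.5 —
#'     benefit only above the critical efficacy 0.3571.}
#'   \item{two_clone_beneficial}{equal halves, (0.8, 0.3, 0.7) and
#'     (0.8, 0.1, 0.2): inhibitor beneficial to both clones for any d.}
#'   \item{two_clone_conditional}{equal halves, (0.9, 0.5, 0.6) and
#'     (0.8, 0.7, 0.7): per-clone critical efficacies 0.19 and 0.93.}
#'   \item{three_clone_sequential}{equal thirds, x = (0.9, 0.8, 0.7),
#'     y = (0.6, 0.7, 0.8), z = (0.4, 0.5, 0.6): ara-C-only cycles shift the
#'     population until a strong inhibitor becomes favourable (after 4
#'     cycles at d = 1).}
#' }
#'
#' @param name One of the configuration names above; omit to get the full
#'   named list.
#' @return A [clone_population()], or a named list of them.
#' @export
example_populations <- function(name = NULL) {
  configs <- list(
    monoclonal_high_samhd1 = clone_population(
      clone("C1", 1, clone_params(0.8, 0.1, 0.7))
    ),
    monoclonal_conditional = clone_population(
      clone("C1", 1, clone_params(0.7, 0.4, 0.5))
    ),
    two_clone_beneficial = clone_population(
      clone("C1", 0.5, clone_params(0.8, 0.3, 0.7)),
      clone("C2", 0.5, clone_params(0.8, 0.1, 0.2))
    ),
    two_clone_conditional = clone_population(
      clone("C1", 0.5, clone_params(0.9, 0.5, 0.6)),
      clone("C2", 0.5, clone_params(0.8, 0.7, 0.7))
    ),
    three_clone_sequential = clone_population(
      clone("C1", 1 / 3, clone_params(0.9, 0.6, 0.4)),
      clone("C2", 1 / 3, clone_params(0.8, 0.7, 0.5)),
      clone("C3", 1 / 3, clone_params(0.7, 0.8, 0.6))
    )
  )
  if (is.null(name)) return(configs)
  if (!name %in% names(configs)) {
    .stop_samclone(sprintf("unknown example '%s'; available: %s", name,
                           paste(names(configs), collapse = ", ")),
                   "samclone_invalid_parameter")
  }
  configs[[name]]
}
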