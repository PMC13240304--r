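# Estimation of the model parameters x, y, z from cell-viability tables,
# replicate-based CV uncertainty, and first-order (delta-method) error
# propagation.
#
# A viability table is a data frame with columns:
#   concentration_uM  ara-C concentration (>= 0)
#   condition         "VPX:<level>" (Vpx-loaded VLPs degrading SAMHD1),
#                     "EMPTY_VLP:<level>" or "NO_VLP" (endogenous SAMHD1
#                     controls)
#   samhd1_relative   optional SAMHD1 level relative to untreated
#   replicate         replicate index
#   viability         surviving fraction in [0, 1]

.VIABILITY_COLS <- c("concentration_uM", "condition", "replicate", "viability")

.check_viability_table <- function(table) {
  missing_cols <- setdiff(.VIABILITY_COLS, names(table))
  if (length(missing_cols)) {
    .stop_samclone(sprintf("viability table lacks column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   "samclone_schema")
  }
  if (any(table$concentration_uM < 0)) {
    .stop_samclone("concentrations must be >= 0", "samclone_schema")
  }
  table$viability <- .check_fraction(table$viability, "viability")
  table
}

.is_null_condition <- function(condition, null_condition) {
  condition == null_condition
}

# Conditions with endogenous SAMHD1: the empty-VLP and no-VLP controls.
.is_control_condition <- function(condition) {
  !startsWith(condition, "VPX")
}

#' Estimate the ara-C efficacy x from SAMHD1-null viabilities
#'
#' In cells whose SAMHD1 has been degraded (100% Vpx-loaded VLPs), y = z = 0
#' and the efficacy model reduces to e = x, so at each ara-C concentration
#' `x = 1 - mean viability`. The standard deviation comes from the
#' replicate spread (sd of the mean) or, with `cv` supplied, from the
#' global relative-error model sd_v = cv * v.
#'
#' @param table Viability table (see package docs for the column contract).
#' @param null_condition Condition label of the SAMHD1-null series.
#' @param cv Optional global coefficient of variation overriding the
#'   replicate-based standard deviations.
#' @return Data frame with one row per concentration: `concentration_uM`,
#'   `x`, `sd`, `n`.
#' @export
estimate_x <- function(table, null_condition = "VPX:100", cv = NULL) {
  table <- .check_viability_table(table)
  sub <- table[.is_null_condition(table$condition, null_condition), ]
  if (nrow(sub) == 0) {
    .stop_samclone(sprintf("no records for null condition '%s'",
                           null_condition),
                   "samclone_missing_condition")
  }
  conc <- sort(unique(sub$concentration_uM))
  res <- lapply(conc, function(cc) {
    v <- sub$viability[sub$concentration_uM == cc]
    m <- mean(v)
    sd_v <- if (!is.null(cv)) {
      cv * m
    } else if (length(v) > 1) {
      stats::sd(v) / sqrt(length(v))
    } else {
      NA_real_
    }
    data.frame(concentration_uM = cc, x = 1 - m, sd = sd_v, n = length(v))
  })
  do.call(rbind, res)
}

#' Estimate the SAMHD1 tumour-suppressor efficacy y per SAMHD1 level
#'
#' Uses only the zero-ara-C records (x = 0), where the efficacy model
#' reduces to e = y, so y = 1 - viability after normalising to the
#' best-surviving condition group. Vpx-treated groups (one per VPX level)
#' are compared against the pooled endogenous-SAMHD1 controls (empty-VLP
#' and no-VLP); the reference is the group with the highest mean viability,
#' so the estimates are invariant to the assay's absolute scale.
#'
#' @param table Viability table.
#' @param zero_concentration Concentration treated as "no ara-C".
#' @param sd_method `"sem"` (standard error of the group mean, default) or
#'   `"sd"` (standard deviation of a single measurement) for the per-group
#'   viability uncertainty entering the ratio.
#' @return Data frame with one row per group: `condition` (VPX levels plus
#'   the pooled `"CONTROL"` group), `y`, `sd`, `n`, `mean_viability`,
#'   and a logical `reference` marking the normalisation group.
#' @export
estimate_y <- function(table, zero_concentration = 0,
                       sd_method = c("sem", "sd")) {
  sd_method <- match.arg(sd_method)
  table <- .check_viability_table(table)
  sub <- table[table$concentration_uM == zero_concentration, ]
  if (nrow(sub) == 0) {
    .stop_samclone("no zero-ara-C records to estimate y from",
                   "samclone_missing_controls")
  }
  group <- ifelse(.is_control_condition(sub$condition), "CONTROL",
                  sub$condition)
  if (!any(group == "CONTROL")) {
    .stop_samclone("no endogenous-SAMHD1 control records at zero ara-C",
                   "samclone_missing_controls")
  }
  groups <- split(sub$viability, group)
  means <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, integer(1))
  sds <- vapply(groups, function(v) {
    if (length(v) > 1) stats::sd(v) else 0
  }, numeric(1))
  if (sd_method == "sem") sds <- sds / sqrt(ns)
  ref <- names(which.max(means))
  ratio <- means / means[[ref]]
  # first-order error of the ratio m_g / m_ref with independent errors
  sd_y <- ratio * sqrt((sds / means)^2 + (sds[[ref]] / means[[ref]])^2)
  sd_y[names(sd_y) == ref] <- 0
  data.frame(
    condition = names(means),
    y = 1 - ratio,
    sd = sd_y,
    n = ns,
    mean_viability = means,
    reference = names(means) == ref,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Invert the efficacy formula for z from a viability measurement
#'
#' Given a measured viability v = 1 - e under known x (ara-C efficacy
#' without SAMHD1) and y (SAMHD1 suppressor efficacy), solving the
#' monoclonal efficacy formula for the SAMHD1 interference gives
#' \deqn{z = \frac{1 - v - y - x + xy}{xy - x}.}
#' Estimates outside \eqn{[0, 1]} — expected near complete protection,
#' where experimental noise pushes the inversion slightly past 1 — are
#' flagged and clamped with a warning; the raw value is kept in the `"raw"`
#' attribute.
#'
#' @param viability Measured surviving fraction in \eqn{[0, 1]}.
#' @param x Ara-C efficacy absent SAMHD1, must be > 0.
#' @param y SAMHD1 suppressor efficacy, must be < 1.
#' @param warn Emit the clamping warning (set `FALSE` when the caller
#'   records the flag itself).
#' @return The z estimate, clamped to \eqn{[0, 1]}; attributes `raw` and
#'   `clamped` record the unclamped value and whether clamping occurred.
#' @export
estimate_z <- function(viability, x, y, warn = TRUE) {
  viability <- .check_fraction(viability, "viability", 1L)
  if (x <= 0 || y >= 1) {
    .stop_samclone("z inversion needs x > 0 and y < 1 (denominator x(y-1) != 0)",
                   "samclone_degenerate_parameter")
  }
  raw <- (1 - viability - y - x + x * y) / (x * y - x)
  clamped <- raw < 0 || raw > 1
  if (clamped && warn) {
    .warn_samclone(sprintf("z estimate %.4g outside [0, 1]; clamped", raw),
                   "samclone_clamped_estimate")
  }
  structure(min(max(raw, 0), 1), raw = raw, clamped = clamped)
}

#' Replicate-based coefficient of variation of viability
#'
#' For each ara-C concentration, pools the viabilities of the named
#' conditions and computes CV = sample SD / mean (n - 1 denominator); the
#' summary is the arithmetic mean of the per-concentration CVs. This sets
#' the relative noise scale sigma_v = CV * v used in error propagation.
#'
#' @param table Viability table.
#' @param conditions Condition labels to pool; defaults to the
#'   endogenous-SAMHD1 controls.
#' @return List with `per_concentration` (data frame `concentration_uM`,
#'   `cv`, `n`) and `mean_cv`.
#' @export
viability_cv <- function(table, conditions = NULL) {
  table <- .check_viability_table(table)
  keep <- if (is.null(conditions)) {
    .is_control_condition(table$condition)
  } else {
    table$condition %in% conditions
  }
  sub <- table[keep, ]
  conc <- sort(unique(sub$concentration_uM))
  per <- lapply(conc, function(cc) {
    v <- sub$viability[sub$concentration_uM == cc]
    if (length(v) < 2) {
      .stop_samclone(sprintf("need >= 2 samples at concentration %g to compute a CV",
                             cc),
                     "samclone_insufficient_replicates")
    }
    data.frame(concentration_uM = cc, cv = stats::sd(v) / mean(v),
               n = length(v))
  })
  per <- do.call(rbind, per)
  list(per_concentration = per, mean_cv = mean(per$cv))
}

#' Delta-method standard deviation of the z estimate
#'
#' First-order propagation through the z inversion (see [estimate_z()])
#' assuming statistically uncorrelated errors in v, x and y:
#' \deqn{\sigma_z^2 = \left(\frac{\partial z}{\partial v}\right)^2 \sigma_v^2 +
#'   \left(\frac{\partial z}{\partial x}\right)^2 \sigma_x^2 +
#'   \left(\frac{\partial z}{\partial y}\right)^2 \sigma_y^2}
#' with analytic partials
#' \eqn{\partial z/\partial v = 1/(x(1-y))},
#' \eqn{\partial z/\partial x = (1-v-y)/(x^2(1-y))},
#' \eqn{\partial z/\partial y = v/(x(1-y)^2)}.
#' The v-partial diverges as x -> 0: z is unidentifiable where ara-C has no
#' effect to protect against.
#'
#' @param viability,x,y The measurement and parameters entering
#'   [estimate_z()].
#' @param sd_viability,sd_x,sd_y Standard deviations of the inputs; by
#'   default sd_viability = cv * viability when `cv` is given.
#' @param cv Optional relative-error model used when `sd_viability` is
#'   missing.
#' @return List with `sd_z` and the evaluated `partials`.
#' @export
propagate_z_sd <- function(viability, x, y, sd_viability = NULL, sd_x = 0,
                           sd_y = 0, cv = NULL) {
  if (is.null(sd_viability)) {
    if (is.null(cv)) {
      .stop_samclone("supply sd_viability or cv", "samclone_invalid_parameter")
    }
    sd_viability <- cv * viability
  }
  if (x <= 0 || y >= 1) {
    .stop_samclone("partials undefined for x = 0 or y = 1",
                   "samclone_degenerate_parameter")
  }
  dz_dv <- 1 / (x * (1 - y))
  dz_dx <- (1 - viability - y) / (x^2 * (1 - y))
  dz_dy <- viability / (x * (1 - y)^2)
  list(
    sd_z = sqrt((dz_dv * sd_viability)^2 + (dz_dx * sd_x)^2 +
                  (dz_dy * sd_y)^2),
    partials = c(dz_dv = dz_dv, dz_dx = dz_dx, dz_dy = dz_dy)
  )
}

#' Dose-response table of x and z across ara-C concentrations
#'
#' Per concentration shared by the SAMHD1-null series and the
#' endogenous-SAMHD1 control series: x from [estimate_x()] on the null
#' series and z from [estimate_z()] on the control-series mean viability,
#' using the endogenous y (estimated from the zero-ara-C rows via
#' [estimate_y()] unless supplied). Standard deviations use the
#' relative-error model sigma_v = cv * v (cv from [viability_cv()] on the
#' control series unless supplied) propagated with [propagate_z_sd()].
#'
#' @param table Viability table containing both series over a shared
#'   concentration grid.
#' @param null_condition Label of the SAMHD1-null series.
#' @param y Endogenous-SAMHD1 suppressor efficacy; estimated when `NULL`.
#' @param sd_y Standard deviation of `y`; taken from [estimate_y()] when
#'   `y` is `NULL`, else 0.
#' @param cv Viability coefficient of variation; estimated when `NULL`.
#' @return Object of class `dose_response_table`: data frame with one row
#'   per concentration (`concentration_uM`, `x`, `x_sd`, `z`, `z_raw`,
#'   `z_clamped`, `z_sd`), with the `y`, `y_sd` and `cv` used attached as
#'   attributes.
#' @export
build_dose_response <- function(table, null_condition = "VPX:100", y = NULL,
                                sd_y = 0, cv = NULL) {
  table <- .check_viability_table(table)
  if (is.null(y)) {
    ytab <- estimate_y(table)
    ctrl <- ytab[ytab$condition == "CONTROL", ]
    y <- ctrl$y
    sd_y <- ctrl$sd
  }
  if (is.null(cv)) {
    cv <- viability_cv(table)$mean_cv
  }
  null_sub <- table[.is_null_condition(table$condition, null_condition), ]
  ctrl_sub <- table[.is_control_condition(table$condition), ]
  if (nrow(null_sub) == 0) {
    .stop_samclone(sprintf("no records for null condition '%s'",
                           null_condition),
                   "samclone_missing_condition")
  }
  conc_null <- sort(unique(null_sub$concentration_uM))
  conc_ctrl <- sort(unique(ctrl_sub$concentration_uM))
  conc <- setdiff(conc_null, 0) # z needs ara-C present (x > 0)
  if (!all(conc %in% conc_ctrl)) {
    .stop_samclone("null and control series do not share a concentration grid",
                   "samclone_concentration_mismatch")
  }
  rows <- lapply(conc, function(cc) {
    v_null <- mean(null_sub$viability[null_sub$concentration_uM == cc])
    v_ctrl <- mean(ctrl_sub$viability[ctrl_sub$concentration_uM == cc])
    x <- 1 - v_null
    sd_x <- cv * v_null
    if (x <= 0) {
      return(data.frame(concentration_uM = cc, x = x, x_sd = sd_x,
                        z = NA_real_, z_raw = NA_real_, z_clamped = NA,
                        z_sd = NA_real_))
    }
    zc <- estimate_z(v_ctrl, x, y, warn = FALSE)
    sd_z <- propagate_z_sd(v_ctrl, x, y, sd_viability = cv * v_ctrl,
                           sd_x = sd_x, sd_y = sd_y)$sd_z
    data.frame(concentration_uM = cc, x = x, x_sd = sd_x,
               z = as.numeric(zc), z_raw = attr(zc, "raw"),
               z_clamped = attr(zc, "clamped"), z_sd = sd_z)
  })
  out <- do.call(rbind, rows)
  attr(out, "y") <- y
  attr(out, "y_sd") <- sd_y
  attr(out, "cv") <- cv
  class(out) <- c("dose_response_table", "data.frame")
  out
}
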