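# Benefit thresholds and regime classification for adding a SAMHD1 inhibitor.
#
# The gain of adding the drug is, in closed form,
#   Delta(d) = e(d) - e(0) = d * (B*d + A),
# with B = alpha*x*y*z >= 0 and A = x*z + alpha*x*y - alpha*y - (1+alpha)*x*y*z.
# For B > 0 the sign of Delta on d in (0, 1] flips exactly at the threshold
# d* = -A/B = (1+alpha)/alpha - 1/z - 1/(alpha*y) + 1/(x*z); for B = 0 the
# gain is linear in d and its sign is the sign of A everywhere.

#' Regime labels for drug-addition benefit
#'
#' @format Character constants: `"ALWAYS_BENEFICIAL"`, `"NEVER_BENEFICIAL"`,
#'   `"CONDITIONAL"`, `"NEUTRAL"`.
#' @name regimes
NULL

.REGIMES <- c("ALWAYS_BENEFICIAL", "NEVER_BENEFICIAL", "CONDITIONAL", "NEUTRAL")

# Vectorised coefficients of Delta(d)/d = B*d + A.
.delta_coefs <- function(x, y, z, alpha) {
  list(A = x * z + alpha * x * y - alpha * y - (1 + alpha) * x * y * z,
       B = alpha * x * y * z)
}

#' Critical inhibitor efficacy separating benefit from harm
#'
#' For interior parameters the drug strictly increases the combined efficacy
#' if and only if its efficacy `d` exceeds
#' \deqn{d^* = \frac{1+\alpha}{\alpha} - \frac{1}{z} - \frac{1}{\alpha y} +
#'   \frac{1}{xz},}
#' which for the symmetric drug (`alpha = 1`) reduces to
#' \eqn{2 - 1/z - 1/y + 1/(xz)}. Thresholds at or below 0 mean the drug is
#' always beneficial; at or above 1, never beneficial on \eqn{d \in (0, 1]}.
#'
#' @inheritParams base_efficacy
#' @param alpha Drug specificity ratio in \eqn{(0, 1]}.
#' @return The threshold as an (extended) real number.
#' @examples
#' benefit_threshold(clone_params(0.7, 0.4, 0.5)) # 0.35714...
#' @export
benefit_threshold <- function(params, alpha = 1) {
  p <- .as_clone_params(params)
  if (p$x * p$y * p$z * alpha == 0) {
    .stop_samclone(
      "benefit threshold undefined for x*y*z*alpha = 0; use classify_regime()",
      "samclone_degenerate_parameter")
  }
  (1 + alpha) / alpha - 1 / p$z - 1 / (alpha * p$y) + 1 / (p$x * p$z)
}

#' Suppressor-dominance condition making the drug detrimental
#'
#' Independently of `x` and `z`, a drug of efficacy `d` and specificity
#' `alpha` is detrimental whenever the SAMHD1 tumour-suppressor efficacy
#' satisfies \eqn{y > 1 / (1 + \alpha - \alpha d)} (symmetric case:
#' \eqn{y > 1/(2 - d)}).
#'
#' @param y SAMHD1 tumour-suppressor efficacy in \eqn{[0, 1]}.
#' @param d Inhibitor efficacy in \eqn{[0, 1]}.
#' @param alpha Specificity ratio in \eqn{[0, 1]}.
#' @return Logical: `TRUE` when the suppressor cost alone makes the drug
#'   detrimental for every `x`, `z`.
#' @export
always_detrimental_by_y <- function(y, d, alpha = 1) {
  y <- .check_fraction(y, "y", 1L)
  d <- .check_fraction(d, "d", 1L)
  alpha <- .check_fraction(alpha, "alpha", 1L)
  y > 1 / (1 + alpha - alpha * d)
}

# Vectorised regime classification. Returns list(regime=character,
# threshold=numeric with -Inf/Inf sentinels and NA for NEUTRAL).
.classify <- function(x, y, z, alpha) {
  co <- .delta_coefs(x, y, z, alpha)
  A <- co$A
  B <- co$B
  n <- length(A)
  regime <- character(n)
  threshold <- numeric(n)
  lin <- B <= .TOL_EQ
  # Linear branch: Delta = A*d.
  regime[lin & A > .TOL_EQ] <- "ALWAYS_BENEFICIAL"
  threshold[lin & A > .TOL_EQ] <- -Inf
  regime[lin & A < -.TOL_EQ] <- "NEVER_BENEFICIAL"
  threshold[lin & A < -.TOL_EQ] <- Inf
  neutral <- lin & abs(A) <= .TOL_EQ
  regime[neutral] <- "NEUTRAL"
  threshold[neutral] <- NA_real_
  # Quadratic branch: threshold -A/B.
  q <- !lin
  thr <- -A[q] / B[q]
  threshold[q] <- thr
  regime[q] <- ifelse(thr <= 0, "ALWAYS_BENEFICIAL",
                      ifelse(thr >= 1, "NEVER_BENEFICIAL", "CONDITIONAL"))
  list(regime = regime, threshold = threshold)
}

#' Classify the benefit regime of adding a SAMHD1 inhibitor
#'
#' Determines, from the closed-form gain \eqn{e(d) - e(0)}, whether adding
#' the inhibitor is beneficial for every `d` in \eqn{(0, 1]}
#' (`ALWAYS_BENEFICIAL`), for none (`NEVER_BENEFICIAL`), only above a
#' critical efficacy strictly inside \eqn{(0, 1)} (`CONDITIONAL`), or has
#' identically zero effect (`NEUTRAL`, e.g. `y = z = 0`). Degenerate
#' parameter combinations (any of `x`, `y`, `z`, `alpha` zero), where the
#' threshold formula divides by zero, are resolved by the analytic sign of
#' the gain rather than by the formula.
#'
#' @inheritParams benefit_threshold
#' @return An object of class `regime_classification`: list with `regime`
#'   (one of the labels above) and `threshold` (critical `d`; `-Inf`/`Inf`
#'   sentinels for the unconditional regimes, `NA` for `NEUTRAL`).
#' @examples
#' classify_regime(clone_params(0.8, 0.1, 0.7)) # always beneficial
#' classify_regime(clone_params(0.7, 0.4, 0.5)) # conditional at 0.357
#' @export
classify_regime <- function(params, alpha = 1) {
  p <- .as_clone_params(params)
  alpha <- .check_fraction(alpha, "alpha", 1L)
  cl <- .classify(p$x, p$y, p$z, alpha)
  structure(list(regime = cl$regime, threshold = cl$threshold),
            class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "undefined" else format(x$threshold)
  cat(sprintf("<regime_classification> %s (threshold d* = %s)\n",
              x$regime, thr))
  invisible(x)
}
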