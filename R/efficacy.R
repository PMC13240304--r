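#' Clone parameters: the inhibitory probabilities (x, y, z)
#'
#' A clone of AML cells is characterised by three probabilities on the unit
#' interval:
#' \describe{
#'   \item{x}{efficacy of ara-C against the clone when SAMHD1 does not
#'     interfere (probability that a cycle of ara-C alone suppresses a cell).}
#'   \item{y}{direct tumour-suppressor efficacy of SAMHD1 against the clone,
#'     independent of ara-C.}
#'   \item{z}{fractional reduction of ara-C efficacy caused by SAMHD1's
#'     ara-CTPase activity (hydrolysis of ara-CTP).}
#' }
#'
#' @param x,y,z Numeric scalars in \eqn{[0, 1]}. Values within 1e-9 of the
#'   interval are accepted and clamped.
#' @return An object of class `clone_params`, a named list with elements
#'   `x`, `y`, `z`.
#' @examples
#' clone_params(0.8, 0.1, 0.7)
#' @export
clone_params <- function(x, y, z) {
  x <- .check_fraction(x, "x", 1L)
  y <- .check_fraction(y, "y", 1L)
  z <- .check_fraction(z, "z", 1L)
  structure(list(x = x, y = y, z = z), class = "clone_params")
}

#' @export
print.clone_params <- function(x, ...) {
  cat(sprintf("<clone_params> x = %g, y = %g, z = %g\n", x$x, x$y, x$z))
  invisible(x)
}

.as_clone_params <- function(params) {
  if (inherits(params, "clone_params")) return(params)
  if (is.numeric(params) && length(params) == 3) {
    return(clone_params(params[[1]], params[[2]], params[[3]]))
  }
  if (is.list(params) && all(c("x", "y", "z") %in% names(params))) {
    return(clone_params(params$x, params$y, params$z))
  }
  .stop_samclone("cannot interpret 'params' as clone parameters (x, y, z)",
                 "samclone_invalid_parameter")
}

#' SAMHD1-inhibitor specification
#'
#' A SAMHD1 inhibitor is described by its efficacy against the ara-CTPase
#' function, `d` (= d_z), and the specificity ratio `alpha` = d_y / d_z,
#' where d_y is the efficacy against the tumour-suppressor function.
#' `alpha = 1` is the symmetric drug (both functions inhibited equally);
#' `alpha -> 0` is a fully ara-CTPase-specific drug.
#'
#' @param d Inhibitor efficacy against the ara-CTPase function, in
#'   \eqn{[0, 1]}.
#' @param alpha Specificity ratio d_y/d_z, in \eqn{[0, 1]}.
#' @return An object of class `drug_spec` with elements `d` and `alpha`.
#' @seealso [drug_spec_from_dy_dz()] for the (d_y, d_z) parameterisation.
#' @examples
#' drug_spec(0.5, alpha = 1)
#' @export
drug_spec <- function(d, alpha = 1) {
  d <- .check_fraction(d, "d", 1L)
  alpha <- .check_fraction(alpha, "alpha", 1L)
  structure(list(d = d, alpha = alpha), class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec> d = %g (ara-CTPase side), alpha = %g (d_y = %g)\n",
              x$d, x$alpha, x$alpha * x$d))
  invisible(x)
}

#' @rdname drug_spec
#' @param d_y,d_z Per-function efficacies; requires `d_y <= d_z` so that
#'   `alpha = d_y/d_z` lies in \eqn{[0, 1]} (drugs at least as effective on
#'   the ara-CTPase side). `d_z = 0` forces `d_y = 0` (the no-drug spec).
#' @export
drug_spec_from_dy_dz <- function(d_y, d_z) {
  d_y <- .check_fraction(d_y, "d_y", 1L)
  d_z <- .check_fraction(d_z, "d_z", 1L)
  if (d_z == 0) {
    if (d_y > 0) {
      .stop_samclone("d_z = 0 with d_y > 0: alpha = d_y/d_z is undefined",
                     "samclone_degenerate_parameter")
    }
    return(drug_spec(0, 1))
  }
  if (d_y > d_z + .TOL_VALID) {
    .stop_samclone("d_y > d_z: alpha would exceed 1",
                   "samclone_invalid_parameter")
  }
  drug_spec(d_z, min(d_y / d_z, 1))
}

#' Per-function efficacies of a drug specification
#'
#' @param drug A [drug_spec()].
#' @return Named numeric vector with `d_y` and `d_z`.
#' @export
drug_dy_dz <- function(drug) {
  c(d_y = drug$alpha * drug$d, d_z = drug$d)
}

# Vectorised efficacy kernel used throughout: reduced parameters under an
# inhibitor with ara-CTPase-side efficacy d and specificity alpha, then the
# two-route independent-survival formula.
.efficacy <- function(x, y, z, d = 0, alpha = 1) {
  y_red <- (1 - alpha * d) * y
  z_red <- (1 - d) * z
  y_red + x - x * z_red - y_red * x + x * y_red * z_red
}

#' Treatment efficacy of ara-C on a monoclonal AML under SAMHD1
#'
#' The clone is suppressed through two statistically independent routes:
#' the ara-C route, whose efficacy is reduced by SAMHD1's ara-CTPase
#' activity to \eqn{(1 - z) x}, and the direct SAMHD1 tumour-suppressor
#' route with efficacy \eqn{y}. The combined efficacy is
#' \deqn{e = y + x - xz - yx + xyz = 1 - (1 - (1 - z)x)(1 - y).}
#'
#' @param params A [clone_params()] object (or a length-3 numeric `c(x, y, z)`).
#' @return The efficacy `e` in \eqn{[0, 1]}: the probability that one
#'   treatment cycle suppresses a cell of this clone; `1 - e` is the
#'   surviving fraction.
#' @examples
#' base_efficacy(clone_params(0.8, 0.1, 0.7)) # 0.316
#' @export
base_efficacy <- function(params) {
  p <- .as_clone_params(params)
  .efficacy(p$x, p$y, p$z)
}

#' Parameter reduction under a SAMHD1 inhibitor
#'
#' The inhibitor lowers both SAMHD1 functions: the tumour-suppressor side by
#' a factor `alpha * d` and the ara-CTPase side by `d`, giving
#' `y_red = (1 - alpha d) y` and `z_red = (1 - d) z`. The improved ara-C
#' efficacy under the drug is `x_imp = (1 - z_red) x`; without the drug it
#' is `x_red = (1 - z) x`.
#'
#' @inheritParams base_efficacy
#' @param drug A [drug_spec()].
#' @return An object of class `reduced_params`: list with `x_red`, `y_red`,
#'   `z_red`, `x_imp`.
#' @export
reduce_params <- function(params, drug) {
  p <- .as_clone_params(params)
  z_red <- (1 - drug$d) * p$z
  structure(list(
    x_red = (1 - p$z) * p$x,
    y_red = (1 - drug$alpha * drug$d) * p$y,
    z_red = z_red,
    x_imp = (1 - z_red) * p$x
  ), class = "reduced_params")
}

#' Combined efficacy of ara-C plus a SAMHD1 inhibitor
#'
#' Evaluates the monoclonal efficacy with the SAMHD1 parameters replaced by
#' their drug-reduced values (see [reduce_params()]):
#' \deqn{e(d) = y_{red} + x - x z_{red} - y_{red} x + x y_{red} z_{red}.}
#' At `d = 0` this equals [base_efficacy()] for every `alpha`; at `d = 1`,
#' `alpha = 1` it equals `x` (full SAMHD1 inhibition).
#'
#' @inheritParams reduce_params
#' @return Efficacy in \eqn{[0, 1]}.
#' @examples
#' combined_efficacy(clone_params(0.7, 0.4, 0.5), drug_spec(1)) # 0.7
#' @export
combined_efficacy <- function(params, drug) {
  p <- .as_clone_params(params)
  .efficacy(p$x, p$y, p$z, drug$d, drug$alpha)
}

#' Monte-Carlo two-route survival simulation
#'
#' Independent stochastic oracle for [combined_efficacy()]: each of
#' `n_cells` cells is killed through the ara-C route with probability
#' `x_imp` and, independently, through the SAMHD1 route with probability
#' `y_red`. Returns the killed fraction with its binomial standard error.
#'
#' @inheritParams reduce_params
#' @param n_cells Number of simulated cells (>= 1).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return List with `efficacy` (killed fraction), `se` (binomial standard
#'   error) and `n_cells`.
#' @export
monte_carlo_efficacy <- function(params, drug = drug_spec(0), n_cells = 1e6,
                                 seed = 1L) {
  if (n_cells < 1) {
    .stop_samclone("n_cells must be >= 1", "samclone_invalid_parameter")
  }
  red <- reduce_params(params, drug)
  killed <- .with_seed(seed, {
    by_arac <- stats::runif(n_cells) < red$x_imp
    by_samhd1 <- stats::runif(n_cells) < red$y_red
    sum(by_arac | by_samhd1)
  })
  p_hat <- killed / n_cells
  list(efficacy = p_hat,
       se = sqrt(p_hat * (1 - p_hat) / n_cells),
       n_cells = n_cells)
}
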