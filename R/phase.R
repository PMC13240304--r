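# Regime classification over (x, y, z) grids and benefit-boundary surfaces.

#' Classify the benefit regime over an (x, y, z) grid
#'
#' Evaluates [classify_regime()] at every point of a regular grid over the
#' unit cube, delineating the regions where adding the SAMHD1 inhibitor is
#' always beneficial, never beneficial, conditionally beneficial (benefit
#' only above a critical d strictly inside (0, 1)) or without effect.
#' Boundary values 0 and 1 on any axis are handled by the degenerate
#' branches of the classification.
#'
#' @param resolution Number of grid points per axis (>= 2), or a length-3
#'   vector for per-axis resolutions. Default 41 per axis.
#' @param alpha Drug specificity ratio.
#' @param x_grid,y_grid,z_grid Optional explicit strictly increasing grids
#'   in \eqn{[0, 1]} overriding `resolution`.
#' @return Object of class `phase_grid`: data frame with columns `x`, `y`,
#'   `z`, `regime`, `threshold`; `alpha` attached as an attribute.
#' @export
classify_grid <- function(resolution = 41, alpha = 1, x_grid = NULL,
                          y_grid = NULL, z_grid = NULL) {
  resolution <- rep_len(resolution, 3)
  if (any(resolution < 2)) {
    .stop_samclone("resolution must be >= 2 per axis",
                   "samclone_invalid_parameter")
  }
  axis <- function(explicit, n) {
    g <- if (is.null(explicit)) seq(0, 1, length.out = n) else explicit
    if (is.unsorted(g, strictly = TRUE) || any(g < 0 | g > 1)) {
      .stop_samclone("axis grids must be strictly increasing within [0, 1]",
                     "samclone_invalid_parameter")
    }
    g
  }
  gx <- axis(x_grid, resolution[1])
  gy <- axis(y_grid, resolution[2])
  gz <- axis(z_grid, resolution[3])
  pts <- expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE)
  cl <- .classify(pts$x, pts$y, pts$z, alpha)
  pts$regime <- cl$regime
  pts$threshold <- cl$threshold
  attr(pts, "alpha") <- alpha
  class(pts) <- c("phase_grid", "data.frame")
  pts
}

#' Benefit-boundary surface z*(x, y) at a given drug efficacy
#'
#' For each (x, y) pair, finds the SAMHD1-interference level z at which the
#' benefit threshold equals `d`: below the surface the drug at efficacy `d`
#' is detrimental, above it beneficial. The threshold is strictly
#' decreasing in z for x < 1 (more ara-C interference to relieve means a
#' weaker drug already pays off), so the root is isolated by bisection on
#' \eqn{z \in (0, 1]} to 1e-10; absence of a root in the interval is
#' recorded as `NA`, not an error.
#'
#' @param x_grid,y_grid Strictly increasing vectors of x and y values in
#'   \eqn{(0, 1]}.
#' @param d Drug efficacy in \eqn{[0, 1]} defining the surface.
#' @param alpha Drug specificity ratio (> 0).
#' @return Data frame in long format: `x`, `y`, `z_star`, `d`, `alpha`.
#' @export
boundary_surface <- function(x_grid, y_grid, d, alpha = 1) {
  d <- .check_fraction(d, "d", 1L)
  if (alpha <= 0) {
    .stop_samclone("alpha must be > 0 for the threshold formula",
                   "samclone_degenerate_parameter")
  }
  thr <- function(x, y, z) {
    (1 + alpha) / alpha - 1 / z - 1 / (alpha * y) + 1 / (x * z)
  }
  grid <- expand.grid(x = x_grid, y = y_grid, KEEP.OUT.ATTRS = FALSE)
  grid$z_star <- mapply(function(x, y) {
    if (x <= 0 || y <= 0) return(NA_real_)
    g <- function(z) thr(x, y, z) - d
    lo <- 1e-12
    hi <- 1
    if (g(hi) > 0 || g(lo) < 0) return(NA_real_) # no root in (0, 1]
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, grid$x, grid$y)
  grid$d <- d
  grid$alpha <- alpha
  grid
}

#' Regime composition of a phase grid
#'
#' @param grid A [classify_grid()] result.
#' @return Named numeric vector: fraction of grid points per regime label
#'   (all four labels present, zeros included); sums to 1.
#' @export
region_fractions <- function(grid) {
  counts <- table(factor(grid$regime, levels = .REGIMES))
  as.vector(counts / nrow(grid)) |> stats::setNames(.REGIMES)
}

#' Static phase-diagram figure
#'
#' Scatter of grid points in the (x, z) plane for a slice of y values,
#' coloured by regime (green: always beneficial; red: never; orange:
#' conditional; grey: neutral). A deliberately thin layer over
#' [classify_grid()] for quick inspection and file export.
#'
#' @param grid A [classify_grid()] result.
#' @param y_value Which y slice to draw (nearest grid value is used).
#' @param file Optional PNG path; when given, the plot is written there.
#' @return Invisibly, the plotted subset.
#' @export
plot_phase_grid <- function(grid, y_value = 0.5, file = NULL) {
  ys <- unique(grid$y)
  y_pick <- ys[which.min(abs(ys - y_value))]
  sub <- grid[grid$y == y_pick, ]
  cols <- c(ALWAYS_BENEFICIAL = "forestgreen", NEVER_BENEFICIAL = "firebrick",
            CONDITIONAL = "darkorange", NEUTRAL = "grey60")
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 700)
    on.exit(grDevices::dev.off())
  }
  plot(sub$x, sub$z, col = cols[sub$regime], pch = 15,
       xlab = "x (ara-C efficacy without SAMHD1)",
       ylab = "z (SAMHD1 interference with ara-C)",
       main = sprintf("Inhibitor-benefit regimes at y = %.3g, alpha = %.3g",
                      y_pick, attr(grid, "alpha")))
  graphics::legend("bottomright", legend = names(cols), col = cols, pch = 15,
                   bg = "white", cex = 0.8)
  invisible(sub)
}
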