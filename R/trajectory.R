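#' Workspace geometry for the reaching task
#'
#' The reaching workspace is a quadrangular table-top region: reaches start at
#' the origin and end on a line `y_end` cm in front of the start. The lateral
#' extent of the enumerated target family spans the full workspace width.
#'
#' @param width lateral extent in cm.
#' @param depth longitudinal extent in cm.
#' @param y_end y coordinate of the finish line in cm (equals `depth` in the
#'   canonical configuration).
#' @return An object of class `"workspace"`: a list with elements `width`,
#'   `depth`, `y_end` and the derived curvature scale `curv_scale` (cm), the
#'   largest scale for which the lateral extremum over the target family stays
#'   at the trajectory endpoints.
#' @export
#' @examples
#' ws <- workspace()
#' ws$curv_scale  # width / 8
workspace <- function(width = 21.7, depth = 7, y_end = depth) {
  stopifnot(is.numeric(width), is.numeric(depth), is.numeric(y_end),
            width > 0, depth > 0, y_end > 0)
  structure(list(width = width, depth = depth, y_end = y_end,
                 curv_scale = width / 8),
            class = "workspace")
}

#' @export
print.workspace <- function(x, ...) {
  cat(sprintf("Reaching workspace: %.4g cm wide x %.4g cm deep (finish line at y = %.4g cm)\n",
              x$width, x$depth, x$y_end))
  cat(sprintf("Curvature scale C = width/8 = %.6g cm\n", x$curv_scale))
  invisible(x)
}

#' Trajectory parameter pair (direction, curvature)
#'
#' A reach trajectory is summarized by two dimensionless parameters: the
#' direction `alpha` (linear lateral drift, right positive) and the curvature
#' `beta` (midpoint-peaked lateral bow vanishing at both ends). Targets lie on
#' a 0.1-spaced grid in \eqn{[-1, 1]^2}; executed parameters may fall outside
#' that range.
#'
#' @param alpha direction parameter, dimensionless, finite.
#' @param beta curvature parameter, dimensionless, finite.
#' @return A named numeric vector `c(alpha = , beta = )` of class
#'   `"traj_params"`.
#' @export
traj_params <- function(alpha, beta) {
  if (length(alpha) != 1L || length(beta) != 1L ||
      !is.numeric(alpha) || !is.numeric(beta) ||
      !is.finite(alpha) || !is.finite(beta)) {
    stop("alpha and beta must be single finite numbers", call. = FALSE)
  }
  structure(c(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "traj_params")
}

#' @export
print.traj_params <- function(x, ...) {
  cat(sprintf("(alpha = %.4g, beta = %.4g)\n", x[["alpha"]], x[["beta"]]))
  invisible(x)
}

# Basis shapes of the trajectory family, evaluated at relative depth u = y/y_end.
# x(u) = alpha * (width/2) * u  +  beta * C * 4 * u * (1 - u),  C = width/8.
traj_basis <- function(u, ws) {
  cbind(direction = ws$width / 2 * u,
        curvature = ws$curv_scale * 4 * u * (1 - u))
}

#' Generate a trajectory from its (direction, curvature) parameters
#'
#' Samples the two-parameter trajectory family
#' \deqn{x(y) = \alpha \frac{W}{2} u + \beta C \, 4 u (1-u), \quad u = y/Y,}
#' with \eqn{W} the workspace width, \eqn{Y} the reach depth and
#' \eqn{C = W/8} the curvature scale calibrated so the enumerated target
#' family exactly fills the workspace. Points are equally spaced in y from 0
#' to `y_end`.
#'
#' @param params a [traj_params] object, or any numeric length-2 vector
#'   `(alpha, beta)`.
#' @param n_points number of samples along the reach (>= 3). The default of
#'   250 echoes one second of movement at the task's ~250 Hz cursor sampling.
#' @param ws a [workspace].
#' @return A data frame of class `"trajectory"` with columns `x_cm`, `y_cm`;
#'   `y_cm` strictly increasing from 0 to `ws$y_end`.
#' @export
#' @examples
#' tr <- generate_trajectory(traj_params(0.5, -0.3))
#' range(tr$y_cm)  # 0 .. 7
generate_trajectory <- function(params, n_points = 250, ws = workspace()) {
  params <- as_traj_params(params)
  stopifnot(length(n_points) == 1L, n_points >= 3)
  y <- seq(0, ws$y_end, length.out = n_points)
  B <- traj_basis(y / ws$y_end, ws)
  x <- B %*% c(params[["alpha"]], params[["beta"]])
  structure(data.frame(x_cm = as.numeric(x), y_cm = y),
            class = c("trajectory", "data.frame"))
}

as_traj_params <- function(p) {
  if (inherits(p, "traj_params")) return(p)
  if (is.numeric(p) && length(p) == 2L) return(traj_params(p[[1L]], p[[2L]]))
  stop("expected a traj_params object or a numeric (alpha, beta) pair",
       call. = FALSE)
}

#' @export
plot.trajectory <- function(x, ...) {
  graphics::plot(x$x_cm, x$y_cm, type = "l", xlab = "x (cm)", ylab = "y (cm)",
                 ...)
  invisible(x)
}

#' Recover (direction, curvature) from a sampled reach path
#'
#' Ordinary least squares of the lateral positions on the two basis shapes of
#' the trajectory family (the family is linear in its parameters, so the fit
#' is closed form). A noiseless generated trajectory round-trips exactly.
#'
#' @param traj a `"trajectory"` data frame, or any data frame with columns
#'   `x_cm` and `y_cm` (>= 3 points, >= 2 distinct nonzero y values).
#' @param ws the [workspace] the trajectory lives in.
#' @return A [traj_params] estimate.
#' @export
#' @examples
#' p <- traj_params(0.3, -0.5)
#' estimate_params(generate_trajectory(p))
estimate_params <- function(traj, ws = workspace()) {
  if (!is.data.frame(traj) || !all(c("x_cm", "y_cm") %in% names(traj))) {
    stop("traj must be a data frame with columns x_cm and y_cm", call. = FALSE)
  }
  if (nrow(traj) < 3L) stop("need at least 3 trajectory points", call. = FALSE)
  y <- traj$y_cm
  if (length(unique(y)) < 2L) {
    stop("degenerate trajectory: all y values equal", call. = FALSE)
  }
  B <- traj_basis(y / ws$y_end, ws)
  # two-unknown linear regression, no intercept (x(0) = 0 by construction)
  coefs <- stats::lm.fit(B, traj$x_cm)$coefficients
  if (anyNA(coefs)) {
    stop("degenerate trajectory: basis shapes are collinear on these samples",
         call. = FALSE)
  }
  traj_params(coefs[["direction"]], coefs[["curvature"]])
}

#' The target parameter grid
#'
#' Target trajectories take direction and curvature values on a 0.1-spaced
#' grid covering \eqn{[-1, 1]}, i.e. 21 values per dimension and 441 targets
#' in all.
#'
#' @return Numeric vector of the 21 grid values (exact multiples of 0.1).
#' @export
target_grid <- function() seq(-10L, 10L) / 10

#' Draw a random target from the parameter grid
#'
#' Both parameters are drawn independently and uniformly from the 21-point
#' 0.1-spaced grid on \eqn{[-1, 1]}. Uses the current R RNG state; seed with
#' [set.seed()] for reproducibility.
#'
#' @return A [traj_params] target.
#' @export
sample_target <- function() {
  g <- target_grid()
  traj_params(sample(g, 1L), sample(g, 1L))
}

#' Bounding box of the enumerated target family
#'
#' Enumerates every target on the parameter grid, densely samples each
#' trajectory, and returns the tight bounding box of the union of points. In
#' the canonical configuration this reproduces the printed workspace extents:
#' 21.7 cm wide by 7 cm deep.
#'
#' @param ws the [workspace] (sets the family's geometric constants).
#' @param grid_values parameter values to enumerate per dimension (defaults to
#'   the full 21-point target grid).
#' @param n_points samples per trajectory.
#' @return A list with `width` (max x - min x), `depth` (max y - min y), and
#'   the raw extents `x_range`, `y_range`, all in cm.
#' @export
family_bounding_box <- function(ws = workspace(), grid_values = target_grid(),
                                n_points = 101) {
  u <- seq(0, 1, length.out = n_points)
  B <- traj_basis(u, ws)
  pars <- expand.grid(alpha = grid_values, beta = grid_values)
  # n_points x n_targets matrix of lateral positions
  X <- B %*% t(as.matrix(pars))
  xr <- range(X)
  yr <- c(0, ws$y_end)
  list(width = diff(xr), depth = diff(yr), x_range = xr, y_range = yr)
}

#' Write or read a trajectory as a two-column CSV
#'
#' @param traj a `"trajectory"` data frame.
#' @param path file path.
#' @return `read_trajectory` returns the `"trajectory"` data frame;
#'   `write_trajectory` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj), all(c("x_cm", "y_cm") %in% names(traj)))
  utils::write.csv(traj[, c("x_cm", "y_cm")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_cm", "y_cm") %in% names(d))) {
    stop("trajectory file must have columns x_cm and y_cm", call. = FALSE)
  }
  structure(d[, c("x_cm", "y_cm")], class = c("trajectory", "data.frame"))
}
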