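#' Flow snapshot container
#'
#' One instant of a time-resolved flow solution: point coordinates, a velocity
#' vector and a pressure per point, plus the time stamp and cycle phase.
#' Synthetic generators attach their analytic ground truth under
#' `attr(snapshot, "ground_truth")`.
#'
#' @param points N x 3 coordinates (m), or a [structured_grid()] (kept so
#'   finite-difference consumers can exploit the structure).
#' @param velocity N x 3 velocity (m/s).
#' @param pressure length-N pressure (Pa).
#' @param t time (s).
#' @param T_period cycle period (s) used to form the phase `t/T`.
#' @return Object of class `flow_snapshot` with fields `points`, `velocity`,
#'   `pressure`, `t`, `phase`, and `grid` (NULL for unstructured input).
#' @export
flow_snapshot <- function(points, velocity, pressure, t = 0, T_period = 1) {
  grid <- if (inherits(points, "structured_grid")) points else NULL
  pts <- .grid_points(points)
  velocity <- as.matrix(velocity)
  stopifnot(ncol(velocity) == 3, nrow(velocity) == nrow(pts),
            length(pressure) == nrow(pts))
  if (!all(is.finite(velocity)) || !all(is.finite(pressure))) {
    stop("non-finite velocity or pressure in snapshot")
  }
  structure(list(points = pts, velocity = velocity, pressure = as.numeric(pressure),
                 t = t, phase = (t / T_period) %% 1, grid = grid),
            class = "flow_snapshot")
}

#' @export
print.flow_snapshot <- function(x, ...) {
  cat(sprintf("flow snapshot: %d points, t = %g s (t/T = %.3f)%s\n",
              nrow(x$points), x$t, x$phase,
              if (is.null(x$grid)) "" else " [structured]"))
  invisible(x)
}

#' Periodic flow series container
#'
#' An ordered sequence of [flow_snapshot()]s covering exactly one period with
#' uniform time step: snapshot times are `t0 + k*dt`, `k = 0..n-1`, with
#' `n*dt = T`, so the frame after the last one is the first again.
#'
#' @param snapshots list of `flow_snapshot`s with strictly increasing `t`.
#' @param T_period the period (s); must equal `n * dt` to 1e-9 relative.
#' @return Object of class `flow_series` with fields `snapshots`, `T_period`,
#'   `dt`, `times`, `phases`.
#' @export
flow_series <- function(snapshots, T_period) {
  stopifnot(length(snapshots) >= 2,
            all(vapply(snapshots, inherits, TRUE, "flow_snapshot")))
  t <- vapply(snapshots, function(s) s$t, 0)
  dt <- diff(t)
  if (any(dt <= 0)) stop("snapshot times must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * mean(dt)) stop("snapshot spacing must be uniform")
  dt <- mean(dt)
  if (abs(length(snapshots) * dt - T_period) > 1e-9 * T_period) {
    stop("series must cover exactly one period: n * dt == T")
  }
  structure(list(snapshots = snapshots, T_period = T_period, dt = dt,
                 times = t, phases = ((t - t[1]) / T_period) %% 1),
            class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("flow series: %d snapshots over T = %g s (dt = %g s)\n",
              length(x$snapshots), x$T_period, x$dt))
  invisible(x)
}

#' @export
length.flow_series <- function(x) length(x$snapshots)

#' Ground truth attached to a synthetic snapshot or series
#'
#' @param x a `flow_snapshot` or `flow_series` produced by a generator.
#' @return The generator's ground-truth list, or NULL.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")
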