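#' Search window for vortex-core tracking
#'
#' A reduced three-dimensional field of view, axis-aligned in the sinus frame,
#' that either stays put or advects downstream with the bulk flow. The core
#' locator only considers candidate points inside the window.
#'
#' @param lo,hi length-3 lower/upper corners in sinus-frame coordinates
#'   (axial, in-plane-1, in-plane-2), m.
#' @param mode `"stationary"` or `"advected"`.
#' @param advection_velocity axial advection speed (m/s), a scalar or a
#'   function of time; required for `"advected"`.
#' @return Object of class `search_window`.
#' @export
search_window <- function(lo, hi, mode = c("stationary", "advected"),
                          advection_velocity = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo))
  if (mode == "advected" && is.null(advection_velocity)) {
    stop("advected window needs an advection_velocity")
  }
  structure(list(lo = lo, hi = hi, mode = mode,
                 advection_velocity = advection_velocity),
            class = "search_window")
}

# axial window offset at time t (relative to t0)
.window_offset <- function(window, t, t0 = 0) {
  if (window$mode == "stationary") return(0)
  v <- window$advection_velocity
  if (is.function(v)) {
    stats::integrate(function(s) vapply(s, v, 0), t0, t)$value
  } else {
    v * (t - t0)
  }
}

#' Locate the vortex-core pressure minimum in a snapshot
#'
#' The vortex core is defined as a local pressure minimum; within the search
#' window the global minimum-pressure candidate point is returned. Candidates
#' are the snapshot points inside the window (optionally restricted to wall
#' faces, with pressure interpolated at the face centers). Ties are broken
#' deterministically: nearest to `prev` if given, otherwise the most
#' upstream (smallest axial coordinate) candidate.
#'
#' @param snapshot a [flow_snapshot()].
#' @param window a [search_window()].
#' @param frame a `sinus_frame` (see [sinus_frame()]); the window lives in
#'   its coordinates.
#' @param wall_restricted restrict candidates to wall faces.
#' @param wall a `wall_patch` (required when `wall_restricted`).
#' @param prev previous core position (length 3, world coordinates) for the
#'   tie-break.
#' @param offset axial window offset (m), e.g. from advection.
#' @return list with `point` (world coords), `xi` (frame coords), `pressure`,
#'   `index` (candidate index).
#' @export
locate_core <- function(snapshot, window, frame, wall_restricted = FALSE,
                        wall = NULL, prev = NULL, offset = 0) {
  stopifnot(inherits(window, "search_window"))
  if (wall_restricted) {
    stopifnot(inherits(wall, "wall_patch"))
    cand_pts <- wall$centers
    # pressure at wall-adjacent samples stands in for the wall pressure
    p <- if (!is.null(snapshot$grid)) {
      interp_trilinear(snapshot$grid, snapshot$pressure, wall$samples)
    } else {
      snapshot$pressure[seq_len(nrow(wall$samples))]
    }
  } else {
    cand_pts <- snapshot$points
    p <- snapshot$pressure
  }
  xi <- to_sinus_frame(frame, cand_pts)
  lo <- window$lo + c(offset, 0, 0); hi <- window$hi + c(offset, 0, 0)
  inside <- xi[, 1] >= lo[1] & xi[, 1] <= hi[1] &
            xi[, 2] >= lo[2] & xi[, 2] <= hi[2] &
            xi[, 3] >= lo[3] & xi[, 3] <= hi[3]
  if (!any(inside)) stop("search window contains no candidate points")
  idx <- which(inside)
  pin <- p[idx]
  if (diff(range(pin)) == 0 && length(idx) > 1L) {
    warning("all candidate pressures equal; returning most-upstream candidate")
    best <- idx[which.min(xi[idx, 1])]
  } else {
    minp <- min(pin)
    best <- idx[pin == minp]
    if (length(best) > 1L) {
      if (!is.null(prev)) {
        d2 <- rowSums(sweep(cand_pts[best, , drop = FALSE], 2, prev)^2)
        best <- best[d2 == min(d2)]
      } else {
        ax <- xi[best, 1]
        best <- best[ax == min(ax)]
      }
      best <- best[1L]
    }
  }
  list(point = cand_pts[best, ], xi = xi[best, ], pressure = p[best], index = best)
}

#' Track the vortex-core pressure minimum over a cycle
#'
#' Applies [locate_core()] to every snapshot, advecting the window per its
#' mode, and expresses the core path in the sinus frame. The core pressure is
#' nondimensionalized by a reference pressure `P0` taken at a reference point
#' at the reference phase (by convention the CCA inlet center at t/T = 0.191).
#' If the core candidates disappear (empty window) for more than `max_miss`
#' consecutive frames, the trajectory is truncated there and flagged as
#' deteriorated.
#'
#' @param series a [flow_series()].
#' @param window a [search_window()].
#' @param frame a `sinus_frame`.
#' @param wall_restricted,wall as in [locate_core()].
#' @param p0_phase reference phase t/T for P0 (default 0.191).
#' @param p0_point reference point (world coords) where P0 is read; NULL
#'   leaves `p_over_P0` as NA.
#' @param max_miss consecutive empty-window frames tolerated before the
#'   track is declared deteriorated (default 3).
#' @return Object of class `core_trajectory`: a data.frame with columns
#'   `t`, `phase`, `x`, `y`, `z`, `xi`, `eta`, `zeta`, `p`, `p_over_P0`;
#'   attributes `P0`, `truncated_at` (phase or NA), `window`, `frame`.
#' @export
track_core <- function(series, window, frame, wall_restricted = FALSE,
                       wall = NULL, p0_phase = 0.191, p0_point = NULL,
                       max_miss = 3L) {
  stopifnot(inherits(series, "flow_series"))
  P0 <- NA_real_
  if (!is.null(p0_point)) {
    iref <- which.min(abs(series$phases - p0_phase))
    sref <- series$snapshots[[iref]]
    P0 <- if (!is.null(sref$grid)) {
      interp_trilinear(sref$grid, sref$pressure, matrix(p0_point, 1))
    } else {
      sref$pressure[which.min(rowSums(sweep(sref$points, 2, p0_point)^2))]
    }
  }
  rows <- list()
  prev <- NULL
  miss <- 0L
  truncated_at <- NA_real_
  t0 <- series$times[1]
  for (i in seq_along(series$snapshots)) {
    s <- series$snapshots[[i]]
    off <- .window_offset(window, s$t, t0)
    res <- tryCatch(
      locate_core(s, window, frame, wall_restricted, wall, prev, off),
      error = function(e) NULL)
    if (is.null(res)) {
      miss <- miss + 1L
      if (miss > max_miss) { truncated_at <- series$phases[i]; break }
      next
    }
    miss <- 0L
    prev <- res$point
    rows[[length(rows) + 1L]] <- data.frame(
      t = s$t, phase = series$phases[i],
      x = res$point[1], y = res$point[2], z = res$point[3],
      xi = res$xi[1], eta = res$xi[2], zeta = res$xi[3],
      p = res$pressure,
      p_over_P0 = if (is.na(P0)) NA_real_ else res$pressure / P0)
  }
  if (length(rows) == 0L) stop("core never found inside the window")
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  structure(traj, P0 = P0, truncated_at = truncated_at,
            window = window, frame = frame,
            class = c("core_trajectory", "data.frame"))
}

#' Core-trajectory kinematics and events
#'
#' Differentiates the axial core coordinate xi(t) to velocity and
#' acceleration (central differences in the interior, one-sided at the ends)
#' after optional moving-average smoothing, and extracts kinematic events:
#' stillstands (zero crossings of the velocity), onsets of upstream motion
#' (velocity sign change + to -) and trajectory deterioration (truncation).
#'
#' @param traj a `core_trajectory`.
#' @param smooth_window moving-average width in frames (odd; 1 = no
#'   smoothing; default 3).
#' @return list with `t`, `phase`, `xi` (smoothed), `velocity` (m/s),
#'   `acceleration` (m/s^2) and `events` (data.frame: phase, type).
#' @export
trajectory_kinematics <- function(traj, smooth_window = 3L) {
  stopifnot(inherits(traj, "core_trajectory"))
  n <- nrow(traj)
  if (n < 3L) stop("need at least 3 phases to differentiate the trajectory")
  stopifnot(smooth_window >= 1L, smooth_window %% 2L == 1L)
  xi <- traj$xi
  if (smooth_window > 1L && n >= smooth_window) {
    half <- (smooth_window - 1L) %/% 2L
    xi_s <- xi
    for (i in seq_len(n)) {
      j <- max(1L, i - half):min(n, i + half)
      xi_s[i] <- mean(xi[j])
    }
    xi <- xi_s
  }
  t <- traj$t
  v <- numeric(n); a <- numeric(n)
  v[2:(n - 1)] <- (xi[3:n] - xi[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (xi[2] - xi[1]) / (t[2] - t[1])
  v[n] <- (xi[n] - xi[n - 1]) / (t[n] - t[n - 1])
  h <- mean(diff(t))
  a[2:(n - 1)] <- (xi[3:n] - 2 * xi[2:(n - 1)] + xi[1:(n - 2)]) / h^2
  a[1] <- a[2]; a[n] <- a[n - 1]

  # zero crossings of the velocity; runs of exact zeros (grid-quantized
  # plateaus) are bridged by interpolating between the flanking nonzero
  # values, which centers the event on the plateau
  events <- data.frame(phase = numeric(0), type = character(0))
  sgn <- sign(v)
  nz <- which(sgn != 0)
  if (length(nz) >= 2L) {
    for (k in seq_len(length(nz) - 1L)) {
      i <- nz[k]; j <- nz[k + 1L]
      if (sgn[i] != sgn[j]) {
        f <- v[i] / (v[i] - v[j])
        ph <- traj$phase[i] + f * (traj$phase[j] - traj$phase[i])
        events <- rbind(events, data.frame(phase = ph, type = "stillstand"))
        if (sgn[i] > 0) {
          events <- rbind(events, data.frame(phase = ph, type = "upstream_onset"))
        }
      }
    }
  }
  trunc <- attr(traj, "truncated_at")
  if (!is.na(trunc)) {
    events <- rbind(events, data.frame(phase = trunc, type = "deterioration"))
  }
  list(t = t, phase = traj$phase, xi = xi, velocity = v, acceleration = a,
       events = events)
}

#' Write a core trajectory to CSV
#'
#' Columns: `t_over_T, xi_m, x, y, z, p_Pa, p_over_P0` plus velocity and
#' acceleration when kinematics are supplied.
#'
#' @param traj a `core_trajectory`.
#' @param path output path.
#' @param kin optional result of [trajectory_kinematics()].
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, kin = NULL) {
  df <- data.frame(t_over_T = traj$phase, xi_m = traj$xi,
                   x = traj$x, y = traj$y, z = traj$z,
                   p_Pa = traj$p, p_over_P0 = traj$p_over_P0)
  if (!is.null(kin)) {
    df$v_m_per_s <- kin$velocity
    df$a_m_per_s2 <- kin$acceleration
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
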