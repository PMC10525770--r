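#' Steady Poiseuille pipe-flow snapshot
#'
#' Fully developed laminar pipe flow along +x with no-slip at `r = a`:
#' `u(r) = 2 U_mean (1 - r^2/a^2)`, zero secondary velocity, and a linear
#' axial pressure `dp/dx = -8 mu U_mean / a^2` (negative, i.e. favorable, for
#' positive flow). The analytic wall shear `4 mu U_mean / a` is attached as
#' ground truth, making this the workhorse oracle for WSS and gradient code.
#'
#' @param a pipe radius (m), > 0.
#' @param U_mean cross-section mean velocity (m/s).
#' @param fluid a [fluid_properties()].
#' @param grid a [structured_grid()] or N x 3 point matrix; pipe axis is the
#'   x-axis through the origin.
#' @param clip if TRUE (default) points with `r > a` are dropped (masked);
#'   with FALSE the analytic profile is evaluated everywhere (useful for
#'   finite-difference fixtures on boxes inscribed in the pipe).
#' @param t,T_period time stamp and period for the snapshot phase.
#' @return A [flow_snapshot()] with ground truth
#'   `list(wss = 4*mu*U_mean/a, dpdx = -8*mu*U_mean/a^2, profile = function(r))`.
#' @export
poiseuille_snapshot <- function(a, U_mean, fluid = fluid_properties(), grid,
                                clip = TRUE, t = 0, T_period = 1) {
  stopifnot(a > 0)
  pts <- .grid_points(grid)
  r2 <- pts[, 2]^2 + pts[, 3]^2
  keep <- rep(TRUE, nrow(pts))
  gr <- if (inherits(grid, "structured_grid")) grid else NULL
  if (clip && any(r2 > a^2)) {
    keep <- r2 <= a^2
    pts <- pts[keep, , drop = FALSE]
    r2 <- r2[keep]
    gr <- NULL   # masking breaks the structured layout
  }
  u <- 2 * U_mean * (1 - r2 / a^2)
  vel <- cbind(u, 0, 0)
  dpdx <- -8 * fluid$mu * U_mean / a^2
  p <- dpdx * pts[, 1]
  snap <- flow_snapshot(if (is.null(gr)) pts else gr, vel, p, t = t, T_period = T_period)
  attr(snap, "ground_truth") <- list(
    kind = "poiseuille", a = a, U_mean = U_mean,
    wss = 4 * fluid$mu * U_mean / a, dpdx = dpdx,
    profile = function(r) 2 * U_mean * (1 - r^2 / a^2),
    mask = keep)
  snap
}

#' Analytic vortex-tube velocity fields
#'
#' Canonical single-structure fields used as lambda2 oracles:
#' \describe{
#'   \item{`lamb_oseen`}{swirl `u_theta(r) = Gamma/(2 pi r) (1 - exp(-r^2/r_c^2))`
#'     about `axis`, with pressure from radial-momentum quadrature
#'     (`dp/dr = rho u_theta^2 / r`, `p(Inf) = 0`).}
#'   \item{`rigid_rotation`}{solid-body rotation `u_theta = omega r`; off-axis
#'     lambda2 is exactly `-omega^2`.}
#'   \item{`simple_shear`}{`u = (gamma * y, 0, 0)`; lambda2 is identically 0
#'     (pure shear carries no vortex).}
#' }
#' The `r = 0` axis is handled by the series limit and never produces NaN.
#'
#' @param kind one of `"lamb_oseen"`, `"rigid_rotation"`, `"simple_shear"`.
#' @param grid a [structured_grid()] or N x 3 point matrix.
#' @param Gamma circulation (m^2/s), for `lamb_oseen`.
#' @param omega angular velocity (1/s), for `rigid_rotation`.
#' @param gamma shear rate (1/s), for `simple_shear`.
#' @param r_c vortex core radius (m), > 0 where applicable.
#' @param axis_point,axis_dir point on and direction of the vortex axis
#'   (defaults: z-axis through the origin).
#' @param fluid a [fluid_properties()] (pressure scaling).
#' @param t,T_period time stamp and period.
#' @return A [flow_snapshot()]; ground truth holds the parameters and, for
#'   `lamb_oseen`, the swirl profile closure and the analytic radius of the
#'   negative-lambda2 core region.
#' @export
vortex_tube_field <- function(kind = c("lamb_oseen", "rigid_rotation", "simple_shear"),
                              grid, Gamma = 1, omega = 1, gamma = 1, r_c = 0.1,
                              axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                              fluid = fluid_properties(), t = 0, T_period = 1) {
  kind <- match.arg(kind)
  pts <- .grid_points(grid)
  n <- nrow(pts)
  d <- axis_dir / sqrt(sum(axis_dir^2))

  if (kind == "simple_shear") {
    vel <- cbind(gamma * pts[, 2], 0, 0)
    snap <- flow_snapshot(grid, vel, rep(0, n), t = t, T_period = T_period)
    attr(snap, "ground_truth") <- list(kind = kind, gamma = gamma, lambda2 = 0)
    return(snap)
  }

  rel <- sweep(pts, 2, axis_point)
  ax <- drop(rel %*% d)                       # axial coordinate
  rad <- rel - outer(ax, d)                   # radial vector
  r <- sqrt(rowSums(rad^2))
  # unit tangential direction: d x rad / r (zero on axis, handled below)
  tang <- cbind(d[2] * rad[, 3] - d[3] * rad[, 2],
                d[3] * rad[, 1] - d[1] * rad[, 3],
                d[1] * rad[, 2] - d[2] * rad[, 1])

  if (kind == "rigid_rotation") {
    vel <- omega * tang                       # |tang| = r so u_theta = omega r
    p <- 0.5 * fluid$rho * omega^2 * r^2
    snap <- flow_snapshot(grid, vel, p, t = t, T_period = T_period)
    attr(snap, "ground_truth") <- list(kind = kind, omega = omega,
                                       lambda2 = -omega^2)
    return(snap)
  }

  # lamb_oseen: factor f(r) with u_vec = f(r) * (d x rad), f = u_theta / r
  stopifnot(r_c > 0)
  f <- .lamb_oseen_factor(r, Gamma, r_c)
  vel <- f * tang
  p <- .lamb_oseen_pressure(r, Gamma, r_c, fluid$rho)
  snap <- flow_snapshot(grid, vel, p, t = t, T_period = T_period)
  attr(snap, "ground_truth") <- list(
    kind = kind, Gamma = Gamma, r_c = r_c,
    u_theta = function(r) .lamb_oseen_factor(r, Gamma, r_c) * r,
    core_radius_lambda2 = .lamb_oseen_l2_radius(Gamma, r_c))
  snap
}

# u_theta / r for a Lamb-Oseen vortex, series-safe at r = 0
.lamb_oseen_factor <- function(r, Gamma, r_c) {
  s <- (r / r_c)^2
  f <- ifelse(s < 1e-8,
              Gamma / (2 * pi * r_c^2) * (1 - s / 2),
              Gamma * (1 - exp(-s)) / (2 * pi * pmax(r, .Machine$double.xmin)^2))
  f
}

# p(r) with p(Inf) = 0 by quadrature of rho u_theta^2 / r
.lamb_oseen_pressure <- function(r, Gamma, r_c, rho) {
  rmax <- max(max(r), 30 * r_c)
  rg <- c(0, exp(seq(log(r_c * 1e-4), log(rmax * 1.0001), length.out = 2000)))
  ut <- .lamb_oseen_factor(rg, Gamma, r_c) * rg
  integrand <- ifelse(rg > 0, rho * ut^2 / pmax(rg, .Machine$double.xmin), 0)
  cum <- c(0, cumsum(0.5 * diff(rg) * (integrand[-1] + integrand[-length(rg)])))
  # far-field tail beyond rmax: u_theta ~ Gamma/(2 pi r) => integral rho G^2/(8 pi^2 r^2)
  tail <- rho * Gamma^2 / (8 * pi^2 * rmax^2)
  pfun <- stats::splinefun(rg, cum - cum[length(cum)] - tail, method = "monoH.FC")
  pfun(r)
}

# radius where lambda2 of the Lamb-Oseen vortex crosses zero (1D root find).
# For planar swirl the nonzero eigenvalues of S^2+O^2 are both
# -(u_theta/r) du_theta/dr, so the crossing sits at the swirl maximum.
.lamb_oseen_l2_radius <- function(Gamma, r_c) {
  uth <- function(r) .lamb_oseen_factor(r, Gamma, r_c) * r
  h <- r_c * 1e-6
  l2 <- function(r) {
    du <- (uth(r + h) - uth(r - h)) / (2 * h)
    -(uth(r) / r) * du
  }
  stats::uniroot(l2, lower = r_c * 1.01, upper = 6 * r_c, tol = 1e-12)$root
}

#' Flow series with a prescribed moving pressure minimum
#'
#' The tracking oracle: pressure is a constant background minus a Gaussian
#' well whose center follows a prescribed trajectory; velocity is a constant
#' bulk velocity. The true trajectory (and its analytic velocity, if given)
#' travels with the series as ground truth.
#'
#' @param trajectory function `t -> c(x, y, z)` (m), the well center path.
#' @param grid a [structured_grid()] or N x 3 point matrix; the well center
#'   must remain inside the bounding box of the points at all sampled times.
#' @param depth well depth (Pa), > 0.
#' @param width Gaussian standard deviation (m), > 0.
#' @param p_background background pressure (Pa).
#' @param bulk_velocity length-3 constant velocity (m/s).
#' @param n_steps snapshots per period.
#' @param T_period period (s).
#' @param velocity_fn optional analytic derivative of `trajectory`
#'   (`t -> c(vx, vy, vz)`); recorded in the ground truth.
#' @return A [flow_series()] with ground truth
#'   `list(trajectory, velocity_fn, positions, times)`.
#' @export
moving_min_series <- function(trajectory, grid, depth = 100, width = 5e-3,
                              p_background = 0, bulk_velocity = c(0, 0, 0),
                              n_steps = 50, T_period = 1, velocity_fn = NULL) {
  stopifnot(is.function(trajectory), depth > 0, width > 0, n_steps >= 2)
  pts <- .grid_points(grid)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  times <- (seq_len(n_steps) - 1) * T_period / n_steps
  centers <- t(vapply(times, trajectory, numeric(3)))
  if (any(sweep(centers, 2, lo) < 0) || any(sweep(centers, 2, hi) > 0)) {
    stop("prescribed well center exits the grid bounding box")
  }
  vel <- matrix(rep(bulk_velocity, each = nrow(pts)), ncol = 3)
  snaps <- lapply(seq_len(n_steps), function(k) {
    d2 <- rowSums(sweep(pts, 2, centers[k, ])^2)
    p <- p_background - depth * exp(-d2 / (2 * width^2))
    flow_snapshot(grid, vel, p, t = times[k], T_period = T_period)
  })
  ser <- flow_series(snaps, T_period)
  attr(ser, "ground_truth") <- list(
    kind = "moving_min", trajectory = trajectory, velocity_fn = velocity_fn,
    positions = centers, times = times, depth = depth, width = width)
  ser
}
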