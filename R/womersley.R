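#' Womersley number
#'
#' `alpha = a * sqrt(omega / nu)` with `omega = 2 pi / T`: the dimensionless
#' frequency parameter of pulsatile pipe flow. For a 3.25 mm radius, T = 1 s
#' and nu = 6.95e-7 m^2/s this is about 9.8, squarely in the physiological
#' carotid range.
#'
#' @param a pipe radius (m).
#' @param T_period period (s).
#' @param nu kinematic viscosity (m^2/s).
#' @param harmonic harmonic index (frequency `harmonic * 2 pi / T`).
#' @return Womersley number, dimensionless.
#' @export
womersley_alpha <- function(a, T_period, nu, harmonic = 1) {
  stopifnot(a > 0, T_period > 0, nu > 0, harmonic >= 1)
  a * sqrt(harmonic * 2 * pi / (T_period * nu))
}

#' Exact pulsatile (Womersley) pipe-flow series
#'
#' The exact unsteady axisymmetric solution of the Navier-Stokes equations in
#' a rigid circular pipe whose cross-section mean velocity reproduces the
#' given inflow waveform harmonic by harmonic. The zero-frequency mode is the
#' Poiseuille profile; each harmonic k contributes the classical Bessel-
#' function profile at Womersley number `alpha_k`. The analytic instantaneous
#' wall shear trace and per-harmonic Womersley numbers are attached as ground
#' truth, so the series doubles as the oracle for finite-difference WSS.
#'
#' @param a pipe radius (m).
#' @param waveform an [make_waveform()] object (its Fourier coefficients are
#'   used directly; no re-fitting).
#' @param fluid a [fluid_properties()].
#' @param grid a [structured_grid()] or N x 3 point matrix; pipe axis = x-axis.
#' @param n_steps snapshots per period.
#' @param clip drop points with `r > a` (see [poiseuille_snapshot()]).
#' @return A [flow_series()]; ground truth holds `tau_wall(t)` (closure),
#'   `tau_wall_series` (sampled at snapshot times), `alpha` (per harmonic),
#'   `u_profile(r, t)` and a truncation-residual estimate.
#' @export
womersley_series <- function(a, waveform, fluid = fluid_properties(), grid,
                             n_steps = 50, clip = TRUE) {
  stopifnot(inherits(waveform, "inflow_waveform"), a > 0, n_steps >= 2)
  T_period <- waveform$T_period
  coef <- waveform$coef                     # one-sided, k = 0..n
  nh <- length(coef) - 1L
  omega <- 2 * pi / T_period
  mu <- fluid$mu; rho <- fluid$rho; nu <- fluid$nu

  # per-harmonic quantities: Lambda_k = i^(3/2) alpha_k
  alpha <- vapply(seq_len(nh), function(k) womersley_alpha(a, T_period, nu, k), 0)
  i32 <- complex(modulus = 1, argument = 3 * pi / 4)
  Lam <- i32 * alpha
  J0L <- .besselJ0_complex(Lam)
  J1L <- .besselJ1_complex(Lam)
  Dk <- 1 - 2 * J1L / (Lam * J0L)           # mean of (1 - J0(Lam r/a)/J0(Lam))

  # complex radial profile per harmonic, normalized to unit mean velocity
  profile_k <- function(k, r) {
    (1 - .besselJ0_complex(Lam[k] * r / a) / J0L[k]) / Dk[k]
  }
  # d(profile)/dr at r = a (J0' = -J1)
  dprof_wall <- (Lam / a) * (J1L / J0L) / Dk

  u_profile <- function(r, t) {
    u <- 2 * Re(coef[1]) * (1 - r^2 / a^2)
    for (k in seq_len(nh)) {
      u <- u + 2 * Re(coef[k + 1L] * profile_k(k, r) * exp(1i * k * omega * t))
    }
    u
  }
  tau_wall <- function(t) {
    # WSS = mu du/dy|wall with y = a - r, so the sign flips relative to du/dr
    tau <- rep(4 * mu * Re(coef[1]) / a, length(t))
    for (k in seq_len(nh)) {
      tau <- tau - mu * 2 * Re(coef[k + 1L] * dprof_wall[k] * exp(1i * k * omega * t))
    }
    tau
  }
  # axial pressure gradient, mode amplitudes P_k with dp/dx = Re sum P_k e^{ikwt}
  Pk <- c(-8 * mu * Re(coef[1]) / a^2 + 0i,
          -1i * rho * omega * seq_len(nh) * coef[-1] / Dk)
  dpdx <- function(t) {
    g <- rep(Re(Pk[1]), length(t))
    for (k in seq_len(nh)) g <- g + 2 * Re(Pk[k + 1L] * exp(1i * k * omega * t))
    g
  }

  pts_all <- .grid_points(grid)
  r2 <- pts_all[, 2]^2 + pts_all[, 3]^2
  gr <- if (inherits(grid, "structured_grid")) grid else NULL
  keep <- rep(TRUE, nrow(pts_all))
  if (clip && any(r2 > a^2)) {
    keep <- r2 <= a^2
    pts_all <- pts_all[keep, , drop = FALSE]
    r2 <- r2[keep]
    gr <- NULL
  }
  r <- sqrt(r2)

  times <- (seq_len(n_steps) - 1) * T_period / n_steps
  snaps <- lapply(seq_along(times), function(j) {
    tj <- times[j]
    u <- u_profile(r, tj)
    p <- dpdx(tj) * pts_all[, 1]
    flow_snapshot(if (is.null(gr)) pts_all else gr, cbind(u, 0, 0), p,
                  t = tj, T_period = T_period)
  })
  ser <- flow_series(snaps, T_period)
  # series truncation residual: magnitude of the last harmonic's mean-velocity
  # contribution relative to the mean flow
  resid <- if (nh > 0) Mod(coef[nh + 1L]) / max(Mod(coef[1]), 1e-300) else 0
  attr(ser, "ground_truth") <- list(
    kind = "womersley", a = a, alpha = alpha,
    tau_wall = tau_wall, tau_wall_series = tau_wall(times),
    u_profile = u_profile, dpdx = dpdx,
    truncation_residual = resid, mask = keep)
  ser
}
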