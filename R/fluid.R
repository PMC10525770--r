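#' Blood-analog fluid properties
#'
#' Bundles the kinematic viscosity, density and (derived) dynamic viscosity
#' used throughout the package. The default kinematic viscosity is the
#' blood-analog value commonly used for Reynolds-matched carotid flow
#' experiments, 6.95e-7 m^2/s; density defaults to 1050 kg/m^3 (whole blood).
#' The dynamic viscosity is always `mu = rho * nu`.
#'
#' @param nu kinematic viscosity in m^2/s, > 0.
#' @param rho density in kg/m^3, > 0.
#' @return An object of class `fluid_properties` with fields `nu`, `rho`, `mu`.
#' @examples
#' fl <- fluid_properties()
#' fl$mu == fl$rho * fl$nu
#' @export
fluid_properties <- function(nu = 6.95e-7, rho = 1050) {
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu), nu > 0,
            is.numeric(rho), length(rho) == 1L, is.finite(rho), rho > 0)
  structure(list(nu = nu, rho = rho, mu = rho * nu), class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("fluid: nu = %.4g m^2/s, rho = %.4g kg/m^3, mu = %.4g Pa s\n",
              x$nu, x$rho, x$mu))
  invisible(x)
}

#' Reynolds number
#'
#' `Re = U * D / nu`: mean velocity times diameter over kinematic viscosity,
#' the convention used for the common-carotid inflow.
#'
#' @param U velocity in m/s (vectorized).
#' @param D diameter in m, > 0.
#' @param nu kinematic viscosity in m^2/s, > 0.
#' @return Reynolds number(s), dimensionless.
#' @export
reynolds <- function(U, D, nu) {
  stopifnot(D > 0, nu > 0)
  U * D / nu
}

#' Resistive outlet boundary model
#'
#' A degenerate (purely resistive) Windkessel: the outlet pressure drop is
#' linear in the instantaneous volume flow rate, `dp = R * Q`.
#'
#' @param R vascular resistance in Pa s/m^3, >= 0.
#' @return An object of class `resistive_outlet`.
#' @seealso [outlet_pressure()]
#' @export
resistive_outlet <- function(R) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R), R >= 0)
  structure(list(R = R), class = "resistive_outlet")
}

#' Pressure drop across a resistive outlet
#'
#' @param outlet a [resistive_outlet()], or a plain resistance in Pa s/m^3.
#' @param Q volume flow rate in m^3/s (vectorized).
#' @return Pressure drop `dp = R * Q` in Pa.
#' @export
outlet_pressure <- function(outlet, Q) {
  R <- if (inherits(outlet, "resistive_outlet")) outlet$R else outlet
  stopifnot(is.numeric(R), R >= 0)
  R * Q
}

#' Continuity flow split at the bifurcation
#'
#' External-carotid outflow is whatever common-carotid inflow is not taken by
#' the internal carotid: `Q_eca = Q_cca - Q_ica`, so mass is conserved exactly.
#'
#' @param Q_cca common carotid inflow rate, m^3/s (vectorized).
#' @param Q_ica internal carotid outflow rate, m^3/s, with `0 <= Q_ica <= Q_cca`.
#' @return `Q_eca` in m^3/s.
#' @export
flow_split <- function(Q_cca, Q_ica) {
  if (any(Q_ica < 0) || any(Q_ica > Q_cca)) {
    stop("continuity violation: need 0 <= Q_ica <= Q_cca")
  }
  Q_cca - Q_ica
}

#' Courant-Friedrichs-Lewy number
#'
#' `CFL = u_max * dt / h`, the stability metric constraining the time step of
#' an explicit transport computation.
#'
#' @param u_max maximum velocity magnitude, m/s.
#' @param dt time step, s, > 0.
#' @param h cell size, m, > 0.
#' @return CFL number, dimensionless.
#' @export
cfl_number <- function(u_max, dt, h) {
  stopifnot(dt > 0, h > 0)
  u_max * dt / h
}

#' Largest time step satisfying a CFL bound
#'
#' @param u_max maximum velocity magnitude, m/s, > 0.
#' @param h cell size, m, > 0.
#' @param cfl_target CFL bound, default 1 (the step returned sits just below it).
#' @return Time step in s such that `cfl_number(u_max, dt, h) < cfl_target`.
#' @export
cfl_max_dt <- function(u_max, h, cfl_target = 1) {
  stopifnot(u_max > 0, h > 0, cfl_target > 0)
  # back off by one ulp-scale factor so the strict inequality holds
  cfl_target * h / u_max * (1 - 1e-12)
}
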