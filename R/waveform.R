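#' Calibrated pulsatile inflow waveform
#'
#' Builds a smooth, strictly periodic surrogate of the patient-averaged
#' common-carotid (CCA) flow waveform: a truncated Fourier series with a
#' sharp systolic peak near `t/T = 0.15` and a gentle diastolic plateau,
#' affinely calibrated so that the Reynolds-number trace `Re(t) = U(t) D / nu`
#' attains exactly the requested peak and period-mean values. The calibration
#' is exact (linear): `U(t) = U_mean + b (s(t) - mean(s))` where `s` is the
#' fixed base shape, so recalibration is idempotent.
#'
#' The default targets are peak Re 1530 and mean Re 385 over a 1 s period at
#' a 6.5 mm inlet, matching Reynolds-matched physiological carotid inflow.
#'
#' @param T_period cardiac period in s.
#' @param peak_Re target maximum Reynolds number over the cycle.
#' @param mean_Re target time-mean Reynolds number; must be < `peak_Re`.
#' @param D inlet diameter in m.
#' @param fluid a [fluid_properties()].
#' @param n_harmonics number of Fourier harmonics retained (>= 4).
#' @param systolic_phase phase `t/T` of the systolic peak of the base shape.
#' @return An object of class `inflow_waveform` with fields `T_period`, `coef`
#'   (complex one-sided Fourier coefficients of `U(t)`, index 0..n_harmonics),
#'   `D`, `nu`, `peak_Re`, `mean_Re`, `U_peak`, `U_mean`.
#' @examples
#' wf <- make_waveform()
#' max(waveform_reynolds(wf, seq(0, 1, length.out = 2000)))
#' @export
make_waveform <- function(T_period = 1, peak_Re = 1530, mean_Re = 385,
                          D = 6.5e-3, fluid = fluid_properties(),
                          n_harmonics = 8, systolic_phase = 0.15) {
  stopifnot(T_period > 0, D > 0, n_harmonics >= 4)
  if (!(peak_Re > mean_Re && mean_Re > 0)) {
    stop("infeasible calibration: need peak_Re > mean_Re > 0")
  }
  U_peak <- peak_Re * fluid$nu / D
  U_mean <- mean_Re * fluid$nu / D

  # base shape on a fine phase grid: systolic pulse + dicrotic/diastolic bump,
  # periodized, then truncated to n_harmonics
  n_fft <- 4096L
  x <- (seq_len(n_fft) - 1) / n_fft
  s_raw <- .wf_base_shape(x, systolic_phase)
  co <- stats::fft(s_raw) / n_fft                 # two-sided coefficients
  coef_s <- co[seq_len(n_harmonics + 1L)]         # one-sided, k = 0..n
  coef_s[1] <- Re(coef_s[1])

  s_mean <- Re(coef_s[1])
  s_max <- .wf_series_max(coef_s, T_period = 1)
  b <- (U_peak - U_mean) / (s_max - s_mean)

  coef <- coef_s * b
  coef[1] <- U_mean + 0i                          # mean term set exactly

  wf <- structure(
    list(T_period = T_period, coef = coef, D = D, nu = fluid$nu,
         peak_Re = peak_Re, mean_Re = mean_Re,
         U_peak = U_peak, U_mean = U_mean),
    class = "inflow_waveform")
  u_min <- min(waveform_velocity(wf, seq(0, T_period, length.out = 4000)))
  if (u_min <= 0) {
    stop("calibrated waveform would reverse at the inlet (peak/mean ratio too large ",
         "for the base shape); reduce peak_Re/mean_Re or adjust the shape")
  }
  wf
}

# systolic Gaussian + diastolic bump, periodized over neighboring cycles
.wf_base_shape <- function(x, systolic_phase) {
  g <- function(x0, sd) {
    v <- 0
    for (k in -1:1) v <- v + exp(-0.5 * ((x - x0 + k) / sd)^2)
    v
  }
  g(systolic_phase, 0.055) + 0.25 * g(systolic_phase + 0.27, 0.10)
}

# exact maximum of a truncated Fourier series: dense grid then local polish
.wf_series_max <- function(coef, T_period) {
  f <- function(t) .wf_eval(coef, t, T_period)
  tg <- seq(0, T_period, length.out = 8192L + 1L)
  vg <- f(tg)
  i <- which.max(vg)
  dt <- tg[2] - tg[1]
  opt <- stats::optimize(f, lower = tg[i] - 2 * dt, upper = tg[i] + 2 * dt,
                         maximum = TRUE, tol = 1e-14)
  max(opt$objective, vg[i])
}

.wf_eval <- function(coef, t, T_period) {
  n <- length(coef) - 1L
  v <- rep(Re(coef[1]), length(t))
  for (k in seq_len(n)) {
    v <- v + 2 * Re(coef[k + 1L] * exp(2i * pi * k * t / T_period))
  }
  v
}

#' Evaluate the inflow waveform velocity
#'
#' @param wf an `inflow_waveform`.
#' @param t times in s (vectorized); the waveform is `T_period`-periodic.
#' @return Spatial-mean inlet velocity U(t) in m/s.
#' @export
waveform_velocity <- function(wf, t) {
  stopifnot(inherits(wf, "inflow_waveform"))
  .wf_eval(wf$coef, t, wf$T_period)
}

#' Reynolds-number trace of the inflow waveform
#'
#' @inheritParams waveform_velocity
#' @return `Re(t) = U(t) * D / nu`.
#' @export
waveform_reynolds <- function(wf, t) {
  reynolds(waveform_velocity(wf, t), wf$D, wf$nu)
}

#' Volume flow-rate trace of the inflow waveform
#'
#' @inheritParams waveform_velocity
#' @return `Q(t) = U(t) * pi D^2 / 4` in m^3/s.
#' @export
waveform_flow_rate <- function(wf, t) {
  waveform_velocity(wf, t) * pi * wf$D^2 / 4
}

#' @export
print.inflow_waveform <- function(x, ...) {
  cat(sprintf("inflow waveform: T = %g s, D = %g mm, peak Re %g / mean Re %g (%d harmonics)\n",
              x$T_period, 1e3 * x$D, x$peak_Re, x$mean_Re, length(x$coef) - 1L))
  invisible(x)
}

#' Write / read a waveform as a two-column CSV
#'
#' The on-disk exchange format is `t_seconds, U_m_per_s`; reading returns a
#' simple sampled waveform usable wherever a velocity trace is needed.
#'
#' @param wf an `inflow_waveform`.
#' @param path output CSV path.
#' @param n_samples number of rows (uniform in time over one period).
#' @return `write_waveform_csv` the path invisibly; `read_waveform_csv` a
#'   data.frame with columns `t_seconds`, `U_m_per_s`.
#' @export
write_waveform_csv <- function(wf, path, n_samples = 200) {
  t <- seq(0, wf$T_period, length.out = n_samples + 1L)[seq_len(n_samples)]
  utils::write.csv(
    data.frame(t_seconds = t, U_m_per_s = waveform_velocity(wf, t)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_seconds", "U_m_per_s") %in% names(df))) {
    stop("waveform CSV must have columns t_seconds, U_m_per_s")
  }
  df
}
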