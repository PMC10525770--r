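#' Axial pressure-gradient trace over the ICA sinus
#'
#' For every phase of the series, takes the area-averaged pressure on two
#' cross-section stations (sinus entry and exit) and forms
#' `dP/dxi = (P_exit - P_entry) / delta_xi`, where `delta_xi` spans the
#' length of the sinus along the ICA center axis. A negative value is a
#' favorable (flow-driving) gradient, a positive value an adverse one.
#'
#' @param series a [flow_series()] on a structured grid.
#' @param entry,exit [cross_section_plane()]s at the sinus entry/exit; their
#'   center separation along `entry$normal` defines `delta_xi`.
#' @param point_probe use the plane-center point pressure instead of the
#'   area average.
#' @return Object of class `axial_gradient_trace`: data.frame with columns
#'   `t`, `phase`, `dP_dxi` (Pa/m); attribute `delta_xi`.
#' @export
axial_pressure_gradient_trace <- function(series, entry, exit,
                                          point_probe = FALSE) {
  stopifnot(inherits(series, "flow_series"),
            inherits(entry, "cross_section_plane"),
            inherits(exit, "cross_section_plane"))
  delta_xi <- sum((exit$center - entry$center) * entry$normal)
  if (delta_xi <= 0) stop("exit station must lie downstream of the entry station")
  station_p <- function(snapshot, pl) {
    if (point_probe) {
      p <- interp_trilinear(snapshot$grid, snapshot$pressure, matrix(pl$center, 1))
      if (is.na(p)) stop("station at plane ", pl$index, " lies outside the domain")
      return(p)
    }
    p <- interp_trilinear(snapshot$grid, snapshot$pressure, pl$samples)
    p <- p[as.vector(pl$mask)]
    if (all(is.na(p))) stop("station at plane ", pl$index, " lies outside the domain")
    mean(p, na.rm = TRUE)
  }
  vals <- vapply(series$snapshots, function(s) {
    if (is.null(s$grid)) stop("pressure-gradient trace needs structured snapshots")
    (station_p(s, exit) - station_p(s, entry)) / delta_xi
  }, 0)
  structure(data.frame(t = series$times, phase = series$phases, dP_dxi = vals),
            delta_xi = delta_xi,
            class = c("axial_gradient_trace", "data.frame"))
}

#' Classify favorable/adverse extrema of a pressure-gradient trace
#'
#' Local minima with negative value are favorable (flow-driving) extrema;
#' local maxima with positive value are adverse. Extrema whose prominence
#' (height above/below the neighboring opposite extrema) falls below
#' `prominence` times the trace range are suppressed. The trace is treated
#' as periodic.
#'
#' @param trace an `axial_gradient_trace` (or data.frame with `phase`,
#'   `dP_dxi`).
#' @param prominence fraction of the trace range (default 0.1).
#' @return data.frame with columns `phase`, `value`, `class`
#'   (`"favorable"`/`"adverse"`); empty when the trace is flat.
#' @export
classify_extrema <- function(trace, prominence = 0.1) {
  v <- trace$dP_dxi
  ph <- trace$phase
  n <- length(v)
  if (n < 5L) stop("need at least 5 phases to classify extrema")
  rng <- diff(range(v))
  if (rng == 0) {
    return(data.frame(phase = numeric(0), value = numeric(0),
                      class = character(0)))
  }
  prv <- v[c(n, seq_len(n - 1L))]
  nxt <- v[c(seq_len(n - 1L) + 1L, 1L)]
  is_min <- v < prv & v <= nxt
  is_max <- v > prv & v >= nxt
  ext_i <- which(is_min | is_max)
  if (length(ext_i) == 0L) {
    return(data.frame(phase = numeric(0), value = numeric(0),
                      class = character(0)))
  }
  # prominence against the neighboring opposite extrema (circular)
  m <- length(ext_i)
  prom <- vapply(seq_len(m), function(k) {
    left <- ext_i[if (k == 1L) m else k - 1L]
    right <- ext_i[if (k == m) 1L else k + 1L]
    min(abs(v[ext_i[k]] - v[left]), abs(v[ext_i[k]] - v[right]))
  }, 0)
  keep <- prom >= prominence * rng
  ext_i <- ext_i[keep]
  out <- data.frame(phase = ph[ext_i], value = v[ext_i],
                    class = ifelse(is_min[ext_i], "favorable", "adverse"))
  out <- out[(out$class == "favorable" & out$value < 0) |
             (out$class == "adverse" & out$value > 0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent differences between paired extrema of two traces
#'
#' Pairs extrema of the same class by nearest phase and reports
#' `(a - b) / |b| * 100` per pair: e.g. -55 means the first trace's extremum
#' is 55% lower in magnitude-signed value than the second's.
#'
#' @param ext_a,ext_b extrema data.frames from [classify_extrema()].
#' @param max_phase_gap maximum |phase difference| for a pairing (t/T units).
#' @return data.frame: `class`, `phase_a`, `phase_b`, `value_a`, `value_b`,
#'   `percent_diff`.
#' @export
compare_extrema <- function(ext_a, ext_b, max_phase_gap = 0.25) {
  out <- list()
  for (cls in intersect(unique(ext_a$class), unique(ext_b$class))) {
    A <- ext_a[ext_a$class == cls, , drop = FALSE]
    B <- ext_b[ext_b$class == cls, , drop = FALSE]
    usedB <- logical(nrow(B))
    for (i in seq_len(nrow(A))) {
      d <- abs(B$phase - A$phase[i])
      d[usedB] <- Inf
      j <- which.min(d)
      if (length(j) == 0L || d[j] > max_phase_gap) next
      usedB[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        class = cls, phase_a = A$phase[i], phase_b = B$phase[j],
        value_a = A$value[i], value_b = B$value[j],
        percent_diff = (A$value[i] - B$value[j]) / abs(B$value[j]) * 100)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(class = character(0), phase_a = numeric(0),
                      phase_b = numeric(0), value_a = numeric(0),
                      value_b = numeric(0), percent_diff = numeric(0)))
  }
  do.call(rbind, out)
}
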