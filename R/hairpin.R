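#' Lambda-shaped hairpin filament polyline
#'
#' A canonical hairpin (Lambda-shaped vortex tube) centerline: two straight
#' legs rising at `tilt` from the wall plane, joined by a semicircular head.
#' Returned as an open polyline suitable for [hairpin_field()].
#'
#' @param span lateral distance between the legs (m).
#' @param height head height above the leg feet (m).
#' @param leg_length length of each straight leg (m).
#' @param tilt leg inclination from the x-axis (degrees).
#' @param origin foot midpoint (length-3).
#' @param n points per piece.
#' @return N x 3 matrix of filament points, ordered foot of leg 1 -> head ->
#'   foot of leg 2.
#' @export
hairpin_filament <- function(span = 0.02, height = 0.015, leg_length = 0.02,
                             tilt = 45, origin = c(0, 0, 0), n = 40) {
  th <- tilt * pi / 180
  half <- span / 2
  # legs rise in +x (streamwise) and +z (wall-normal)
  foot1 <- origin + c(0, -half, 0)
  foot2 <- origin + c(0, +half, 0)
  top1 <- foot1 + c(leg_length * cos(th), 0, leg_length * sin(th))
  top2 <- foot2 + c(leg_length * cos(th), 0, leg_length * sin(th))
  s <- seq(0, 1, length.out = n)
  leg1 <- outer(1 - s, foot1) + outer(s, top1)
  # arc from top1 to top2 bulging upward in z (head of the hairpin)
  phi <- seq(-pi / 2, pi / 2, length.out = n)
  head <- cbind(rep(top1[1], n),
                origin[2] + half * sin(phi),
                top1[3] + (height - leg_length * sin(th)) * cos(phi))
  leg2 <- outer(s, foot2) + outer(1 - s, top2)
  rbind(leg1, head[-1, , drop = FALSE], leg2[-1, , drop = FALSE])
}

#' Velocity field induced by a vortex filament (Biot-Savart)
#'
#' Integrates the Biot-Savart law over an open or closed filament polyline
#' with Gaussian (Lamb-Oseen) core regularization
#' `q(x) = erf(x) - (2/sqrt(pi)) x exp(-x^2)`, `x = |r|/r_c`, which reproduces
#' the Lamb-Oseen swirl profile exactly in the straight-filament limit. The
#' quadrature refines the filament discretization until the maximum velocity
#' change falls below `tol`.
#'
#' @param filament N x 3 matrix of filament points (polyline), or a function
#'   `s in [0,1] -> c(x,y,z)`.
#' @param Gamma circulation (m^2/s); `Gamma = 0` returns the background only.
#' @param r_c Gaussian core radius (m), > 0.
#' @param grid a [structured_grid()] or N x 3 point matrix.
#' @param background length-3 uniform background velocity (m/s).
#' @param fluid a [fluid_properties()] (for the Bernoulli pressure estimate).
#' @param tol absolute quadrature tolerance on velocity (m/s).
#' @param n0 initial number of filament segments.
#' @param max_refine maximum number of refinement doublings.
#' @param t,T_period time stamp and period.
#' @return A [flow_snapshot()]; pressure is the Bernoulli estimate
#'   `-rho |u|^2 / 2` (minimum along the core). Ground truth holds the
#'   filament polyline, `Gamma`, `r_c` and the converged segment count.
#' @export
hairpin_field <- function(filament, Gamma, r_c, grid, background = c(0, 0, 0),
                          fluid = fluid_properties(), tol = 1e-8, n0 = 256,
                          max_refine = 6, t = 0, T_period = 1) {
  stopifnot(r_c > 0, tol > 0)
  pts <- .grid_points(grid)
  np <- nrow(pts)
  bg <- matrix(rep(background, each = np), ncol = 3)

  fil_fun <- if (is.function(filament)) {
    filament
  } else {
    fp <- as.matrix(filament)
    stopifnot(ncol(fp) == 3, nrow(fp) >= 2)
    sknots <- c(0, cumsum(sqrt(rowSums(diff(fp)^2))))
    sknots <- sknots / sknots[length(sknots)]
    fx <- stats::approxfun(sknots, fp[, 1]); fy <- stats::approxfun(sknots, fp[, 2])
    fz <- stats::approxfun(sknots, fp[, 3])
    function(s) cbind(fx(s), fy(s), fz(s))
  }
  sample_fil <- function(n) {
    s <- seq(0, 1, length.out = n + 1L)
    p <- fil_fun(s)
    if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = FALSE)
    p
  }
  # crude self-intersection guard: non-neighboring nodes closer than r_c/10
  chk <- sample_fil(200L)
  dmin <- Inf
  for (i in seq_len(nrow(chk) - 4L)) {
    d2 <- rowSums(sweep(chk[(i + 4L):nrow(chk), , drop = FALSE], 2, chk[i, ])^2)
    dmin <- min(dmin, d2)
  }
  if (sqrt(dmin) < r_c / 10 && Gamma != 0) {
    stop("filament self-intersects (non-adjacent points closer than r_c/10)")
  }

  if (Gamma == 0) {
    snap <- flow_snapshot(grid, bg, -0.5 * fluid$rho * rowSums(bg^2),
                          t = t, T_period = T_period)
    attr(snap, "ground_truth") <- list(kind = "hairpin", filament = chk,
                                       Gamma = 0, r_c = r_c, n_segments = 0L)
    return(snap)
  }

  induced <- function(n) {
    fp <- sample_fil(n)
    mid <- (fp[-1, , drop = FALSE] + fp[-nrow(fp), , drop = FALSE]) / 2
    dl <- diff(fp)
    u <- matrix(0, np, 3)
    for (j in seq_len(nrow(mid))) {
      rx <- pts[, 1] - mid[j, 1]; ry <- pts[, 2] - mid[j, 2]; rz <- pts[, 3] - mid[j, 3]
      rr <- sqrt(rx^2 + ry^2 + rz^2)
      rr <- pmax(rr, 1e-30)
      x <- rr / r_c
      q <- (2 * stats::pnorm(x * sqrt(2)) - 1) - (2 / sqrt(pi)) * x * exp(-x^2)
      w <- Gamma / (4 * pi) * q / rr^3
      u[, 1] <- u[, 1] + w * (dl[j, 2] * rz - dl[j, 3] * ry)
      u[, 2] <- u[, 2] + w * (dl[j, 3] * rx - dl[j, 1] * rz)
      u[, 3] <- u[, 3] + w * (dl[j, 1] * ry - dl[j, 2] * rx)
    }
    u
  }

  n <- as.integer(n0)
  u_prev <- induced(n)
  converged <- FALSE
  for (it in seq_len(max_refine)) {
    n <- 2L * n
    u_new <- induced(n)
    err <- max(abs(u_new - u_prev))
    u_prev <- u_new
    if (err < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf(paste0("Biot-Savart quadrature did not converge: ",
                        "last refinement change %.3e m/s at %d segments ",
                        "(tol %.1e)"), err, n, tol))
  }
  u <- u_prev + bg
  snap <- flow_snapshot(grid, u, -0.5 * fluid$rho * rowSums(u^2),
                        t = t, T_period = T_period)
  attr(snap, "ground_truth") <- list(kind = "hairpin", filament = sample_fil(n),
                                     Gamma = Gamma, r_c = r_c, n_segments = n)
  snap
}
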