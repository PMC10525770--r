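#' Cylindrical pipe wall patch
#'
#' A wall-face set on the cylinder `r = a` (axis = x-axis) with outward unit
#' normals and wall-adjacent interior sample points at wall distance `y`
#' (and `2y` for the second-order derivative option). Used as the fixture
#' wall for the analytic pipe-flow oracles.
#'
#' @param a pipe radius (m).
#' @param x0,L axial start and length of the patch (m).
#' @param n_theta,n_x circumferential / axial face counts.
#' @param y wall-normal distance of the interior sample points (m).
#' @return Object of class `wall_patch` with fields `centers`, `normals`,
#'   `areas`, `samples`, `samples2`, `y`.
#' @export
pipe_wall_patch <- function(a, x0 = 0, L = 0.01, n_theta = 32L, n_x = 8L,
                            y = a / 50) {
  stopifnot(a > 0, L > 0, y > 0, y < a)
  th <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  xs <- x0 + (seq_len(n_x) - 0.5) * L / n_x
  gg <- expand.grid(th = th, x = xs)
  nrm <- cbind(0, cos(gg$th), sin(gg$th))
  centers <- cbind(gg$x, a * cos(gg$th), a * sin(gg$th))
  samples <- cbind(gg$x, (a - y) * cos(gg$th), (a - y) * sin(gg$th))
  samples2 <- cbind(gg$x, (a - 2 * y) * cos(gg$th), (a - 2 * y) * sin(gg$th))
  structure(list(centers = centers, normals = nrm,
                 areas = rep(a * (2 * pi / n_theta) * (L / n_x), nrow(centers)),
                 samples = samples, samples2 = samples2, y = y),
            class = "wall_patch")
}

#' Wall patch from a surface mesh
#'
#' Converts (a subset of) the faces of a triangulated vessel surface into a
#' wall patch: face centroids, outward normals, areas, and interior sample
#' points offset inward along the face normal.
#'
#' @param mesh a mesh list with `vertices` (V x 3) and `faces` (F x 3 indices)
#'   and outward `normals` (F x 3), e.g. the `surface` of a built geometry.
#' @param y inward offset of the sample points (m).
#' @param face_subset optional integer face indices.
#' @return A `wall_patch`.
#' @export
wall_patch_from_mesh <- function(mesh, y, face_subset = NULL) {
  f <- mesh$faces
  if (!is.null(face_subset)) f <- f[face_subset, , drop = FALSE]
  v <- mesh$vertices
  centers <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  nrm <- mesh$normals
  if (!is.null(face_subset)) nrm <- nrm[face_subset, , drop = FALSE]
  structure(list(centers = centers, normals = nrm, areas = areas,
                 samples = centers - y * nrm, samples2 = centers - 2 * y * nrm,
                 y = y),
            class = "wall_patch")
}

#' @export
print.wall_patch <- function(x, ...) {
  cat(sprintf("wall patch: %d faces, sample distance y = %g m\n",
              nrow(x$centers), x$y))
  invisible(x)
}

#' Instantaneous wall shear stress
#'
#' `WSS = tau_w = mu (du/dy)_wall`: the wall-tangential viscous traction,
#' evaluated from the no-slip condition and the velocity at the wall-adjacent
#' sample point(s). The default is the first-order one-sided derivative
#' `mu * u_t(y) / y`; `order = 2` uses the two-point second-order
#' extrapolation `mu * (4 u_t(y) - u_t(2y)) / (2y)`. The wall-normal velocity
#' component is removed by tangent-plane projection, so the WSS vector is
#' tangent to the wall by construction.
#'
#' Velocity at the sample points is taken from the snapshot: trilinearly
#' interpolated on structured snapshots, or matched point-for-point when the
#' snapshot was generated directly on `rbind(wall$samples, wall$samples2)` or
#' on `wall$samples`.
#'
#' @param snapshot a [flow_snapshot()].
#' @param wall a `wall_patch`.
#' @param fluid a [fluid_properties()].
#' @param order derivative order, 1 (default) or 2.
#' @return Object of class `wss_field`: `tau` (F x 3, Pa), `mag` (Pa),
#'   `phase`, `t`, `order`, plus the `fluid` used (recorded for provenance).
#' @export
compute_wss <- function(snapshot, wall, fluid = fluid_properties(), order = 1L) {
  stopifnot(inherits(wall, "wall_patch"), order %in% c(1L, 2L))
  nf <- nrow(wall$centers)
  u1 <- .sample_velocity(snapshot, wall$samples)
  u2 <- if (order == 2L) .sample_velocity(snapshot, wall$samples2, offset = nf) else NULL
  tangential <- function(u) u - wall$normals * rowSums(u * wall$normals)
  ut1 <- tangential(u1)
  tau <- if (order == 1L) {
    fluid$mu * ut1 / wall$y
  } else {
    fluid$mu * (4 * ut1 - tangential(u2)) / (2 * wall$y)
  }
  structure(list(tau = tau, mag = sqrt(rowSums(tau^2)),
                 phase = snapshot$phase, t = snapshot$t, order = order,
                 fluid = fluid),
            class = "wss_field")
}

.sample_velocity <- function(snapshot, xyz, offset = 0L) {
  n <- nrow(xyz)
  if (!is.null(snapshot$grid)) {
    u <- interp_trilinear(snapshot$grid, snapshot$velocity, xyz)
    if (any(is.na(u))) stop(sum(is.na(u[, 1])), " sample points outside the fluid domain")
    return(u)
  }
  idx <- seq_len(n) + offset
  if (nrow(snapshot$points) < max(idx)) {
    stop("unstructured snapshot does not cover the wall sample points")
  }
  d <- max(abs(snapshot$points[idx, , drop = FALSE] - xyz))
  if (d > 1e-9) {
    stop("unstructured snapshot points do not coincide with wall samples ",
         "(max offset ", format(d), " m); generate the snapshot on the sample points")
  }
  snapshot$velocity[idx, , drop = FALSE]
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("WSS at %d faces, t/T = %.3f: |tau| in [%.3g, %.3g] Pa (order %d)\n",
              nrow(x$tau), x$phase, min(x$mag), max(x$mag), x$order))
  invisible(x)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) integral_0^T |tau_w| dt` per wall face. The snapshots must
#' sample one full period uniformly (times `k*dt`, `n*dt = T`); the periodic
#' trapezoidal rule then reduces to the arithmetic mean over phases.
#'
#' @param wss_list list of `wss_field`s over one period.
#' @param T_period the period (s).
#' @return Object of class `tawss_field` with field `tawss` (Pa per face).
#' @export
compute_tawss <- function(wss_list, T_period) {
  stopifnot(length(wss_list) >= 1,
            all(vapply(wss_list, inherits, TRUE, "wss_field")))
  t <- vapply(wss_list, function(w) w$t, 0)
  n <- length(t)
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
      stop("WSS phases must be strictly increasing and uniformly spaced")
    }
    if (abs(n * mean(dt) - T_period) > 1e-6 * T_period) {
      stop("WSS snapshots must cover exactly one period (n * dt == T)")
    }
  }
  nf <- nrow(wss_list[[1]]$tau)
  mags <- matrix(vapply(wss_list, function(w) w$mag, numeric(nf)), nrow = nf)
  structure(list(tawss = rowMeans(mags), n_phases = n,
                 T_period = T_period),
            class = "tawss_field")
}

#' Spatial overlap of the high-WSS band with the vortex wall footprint
#'
#' Quantifies how well the band of elevated instantaneous WSS coincides with
#' the wall projection of the vortex regions: the high-WSS set is the faces
#' above the `q`-quantile of `|tau_w|`; the footprint is the faces whose
#' center lies within distance `d` of any vortex-region member point. The
#' returned Szymkiewicz-Simpson coefficient
#' `|A intersect B| / min(|A|, |B|)` is 1 when one set contains the other and
#' 0 when they are disjoint (or either set is empty, with a warning).
#'
#' @param wss a `wss_field`.
#' @param regions list of `vortex_region`s (same phase and geometry).
#' @param wall the `wall_patch` the WSS lives on.
#' @param q WSS quantile defining the high-WSS band (default 0.8: top 20%).
#' @param d projection distance (m).
#' @return Overlap coefficient in [0, 1], with attributes `high_wss_faces`
#'   and `footprint_faces` (index vectors).
#' @export
wss_vortex_overlap <- function(wss, regions, wall, q = 0.8, d) {
  stopifnot(inherits(wss, "wss_field"), inherits(wall, "wall_patch"), d > 0)
  high <- which(wss$mag > stats::quantile(wss$mag, q, names = FALSE))
  if (length(regions) == 0L) {
    warning("no vortex regions: overlap is 0")
    return(structure(0, high_wss_faces = high, footprint_faces = integer(0)))
  }
  vpts <- do.call(rbind, lapply(regions, function(r) r$points))
  foot <- which(vapply(seq_len(nrow(wall$centers)), function(i) {
    min(rowSums(sweep(vpts, 2, wall$centers[i, ])^2)) <= d^2
  }, TRUE))
  if (length(foot) == 0L || length(high) == 0L) {
    warning("empty high-WSS set or vortex footprint: overlap is 0")
    return(structure(0, high_wss_faces = high, footprint_faces = foot))
  }
  ov <- length(intersect(high, foot)) / min(length(high), length(foot))
  structure(ov, high_wss_faces = high, footprint_faces = foot)
}
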