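#' Build a watertight parametric carotid-bifurcation surface
#'
#' Constructs the bifurcation as the smooth union of three straight-axis
#' canal surfaces (CCA, ICA with sinus bulge, ECA) capped at the open ends,
#' extracts a watertight triangulated surface by marching tetrahedra with
#' vertices projected onto the exact implicit surface, and attaches branch
#' centerlines, per-face branch labels and the radius profiles.
#'
#' Coordinate convention: the CCA axis runs along +x with the bifurcation
#' apex at the origin; the bifurcation plane is z = 0 with the ICA on the
#' +y side.
#'
#' @param params a [cab_parameters()] (or [cab_preset()]).
#' @param h target mesh cell size (m); default is 30% of the smallest branch
#'   radius, which resolves every lumen while keeping meshes light (vertex
#'   projection makes measured dimensions independent of `h`).
#' @return Object of class `cab_geometry`: `surface` (list `vertices`,
#'   `faces`, `normals`, `labels` in {cca, ica, eca, sinus}), `centerlines`
#'   (per branch: x, y, z, arclength), `apex`, `branch_dirs`, `radius_fns`
#'   (per-branch radius profile closures), `sinus_segment` (arc range on the
#'   ICA), `params`, `sdf` (the implicit function), `h`.
#' @export
build_geometry <- function(params, h = NULL) {
  validate_cab_parameters(params)
  p <- params
  r_in <- p$cca_inlet_diameter / 2
  r_apex <- r_in * p$cca_taper_ratio
  r_ica <- p$ica_cca_diameter_ratio * r_in
  r_sin <- p$sinus_max_diameter / 2
  r_eca <- p$eca_diameter / 2
  th_i <- p$ica_branch_angle * pi / 180
  th_e <- p$eca_branch_angle * pi / 180

  apex <- c(0, 0, 0)
  dir_cca <- c(1, 0, 0)
  dir_ica <- c(cos(th_i), sin(th_i), 0)
  dir_eca <- c(cos(th_e), -sin(th_e), 0)
  L_cca <- p$entry_length
  s0 <- p$sinus_offset; Ls <- p$sinus_length
  L_ica <- s0 + Ls + p$ica_exit_length
  L_eca <- s0 + p$eca_exit_length
  base_cca <- apex - L_cca * dir_cca

  # radius profiles (s = arc length from the branch start)
  smooth01 <- function(u) { u <- pmin(pmax(u, 0), 1); u * u * (3 - 2 * u) }
  rf_cca <- function(s) r_in + (r_apex - r_in) * s / L_cca
  rf_ica <- function(s) {
    r <- r_apex + (r_ica - r_apex) * smooth01(s / s0)
    bulge <- (s >= s0 & s <= s0 + Ls)
    r[bulge] <- r_ica + (r_sin - r_ica) * sin(pi * (s[bulge] - s0) / Ls)^2
    # the blend may undershoot where r_ica < r_apex and the bulge begins
    r
  }
  rf_eca <- function(s) r_apex + (r_eca - r_apex) * smooth01(s / s0)

  # the branch tubes overlap at the junction by design, but must separate
  # once and stay separate (a sinus bulge re-touching the ECA is an error)
  schk <- seq(s0, min(L_ica, L_eca), length.out = 120)
  pi_pts <- matrix(apex, length(schk), 3, byrow = TRUE) + outer(schk, dir_ica)
  pe_pts <- matrix(apex, length(schk), 3, byrow = TRUE) + outer(schk, dir_eca)
  gap <- sqrt(rowSums((pi_pts - pe_pts)^2)) - (rf_ica(schk) + rf_eca(schk))
  sep <- which(gap > 0)
  if (length(sep) == 0L) {
    stop("construction error: ICA and ECA never separate (total angle too ",
         "small for these diameters)")
  }
  if (any(gap[sep[1]:length(gap)] < 0)) {
    stop("construction error: ICA and ECA surfaces re-intersect downstream ",
         "of the bifurcation (sinus bulge too wide for this branch angle)")
  }

  k <- p$fillet_radius
  sdf <- function(pts) {
    pts <- as.matrix(pts)
    d <- .canal_field(pts, base_cca, dir_cca, L_cca, rf_cca)
    d <- .smin(d, .canal_field(pts, apex, dir_ica, L_ica, rf_ica), k)
    d <- .smin(d, .canal_field(pts, apex, dir_eca, L_eca, rf_eca), k)
    rel <- sweep(pts, 2, apex)
    caps <- pmax(-(drop(rel %*% dir_cca) + L_cca),
                 drop(rel %*% dir_ica) - L_ica,
                 drop(rel %*% dir_eca) - L_eca)
    pmax(d, caps)
  }

  if (is.null(h)) h <- 0.3 * min(r_ica, r_eca, r_apex)
  rmax <- max(r_in, r_sin, r_eca)
  ends <- rbind(base_cca, apex + L_ica * dir_ica, apex + L_eca * dir_eca, apex)
  lo <- apply(ends, 2, min) - rmax - 3 * h
  hi <- apply(ends, 2, max) + rmax + 3 * h
  gx <- seq(lo[1], hi[1], by = h); gy <- seq(lo[2], hi[2], by = h)
  gz <- seq(lo[3], hi[3], by = h)
  mesh <- .iso_surface(sdf, gx, gy, gz)

  wt <- mesh_is_watertight(mesh)
  if (!wt$watertight) {
    stop("construction error: extracted surface is not watertight (",
         wt$n_boundary_edges, " boundary / ", wt$n_nonmanifold_edges,
         " non-manifold edges)")
  }

  # per-face branch labels from the nearest unblended canal field
  cent <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
             mesh$vertices[mesh$faces[, 3], ]) / 3
  dmat <- cbind(cca = .canal_field(cent, base_cca, dir_cca, L_cca, rf_cca),
                ica = .canal_field(cent, apex, dir_ica, L_ica, rf_ica),
                eca = .canal_field(cent, apex, dir_eca, L_eca, rf_eca))
  labels <- c("cca", "ica", "eca")[max.col(-dmat)]
  s_ica <- drop(sweep(cent, 2, apex) %*% dir_ica)
  labels[labels == "ica" & s_ica >= s0 & s_ica <= s0 + Ls] <- "sinus"

  cl <- function(base, dir, L, n = 80) {
    s <- seq(0, L, length.out = n)
    data.frame(x = base[1] + s * dir[1], y = base[2] + s * dir[2],
               z = base[3] + s * dir[3], arclength = s)
  }
  structure(list(
    surface = c(mesh, list(labels = labels)),
    centerlines = list(cca = cl(base_cca, dir_cca, L_cca),
                       ica = cl(apex, dir_ica, L_ica),
                       eca = cl(apex, dir_eca, L_eca)),
    apex = apex,
    branch_dirs = list(cca = dir_cca, ica = dir_ica, eca = dir_eca),
    branch_lengths = list(cca = L_cca, ica = L_ica, eca = L_eca),
    radius_fns = list(cca = rf_cca, ica = rf_ica, eca = rf_eca),
    sinus_segment = c(s0, s0 + Ls),
    params = p, sdf = sdf, h = h),
    class = "cab_geometry")
}

#' @export
print.cab_geometry <- function(x, ...) {
  cat(sprintf("CAB geometry: %d vertices / %d faces (h = %.3g mm), ICA %g deg, ECA %g deg\n",
              nrow(x$surface$vertices), nrow(x$surface$faces), 1e3 * x$h,
              x$params$ica_branch_angle, x$params$eca_branch_angle))
  invisible(x)
}

# diameter of the lumen cross-section at arc station s of a branch, by
# radial ray-casting on the implicit surface in the station plane
.section_diameter <- function(geom, branch, s, n_rays = 32L) {
  dir <- geom$branch_dirs[[branch]]
  base <- if (branch == "cca") {
    geom$apex - geom$branch_lengths$cca * dir
  } else {
    geom$apex
  }
  c0 <- base + s * dir
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - dir * sum(ref * dir); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2], dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  th <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  dirs <- outer(cos(th), e1) + outer(sin(th), e2)
  # stay local: just past the largest possible lumen radius at this station
  rmax <- 0.75 * max(geom$params$sinus_max_diameter, geom$params$cca_inlet_diameter)
  tlo <- rep(0, n_rays); thi <- rep(rmax, n_rays)
  fhi <- geom$sdf(matrix(c0, n_rays, 3, byrow = TRUE) + rmax * dirs)
  if (any(fhi < 0)) stop("section ray did not exit the lumen; station too close to a junction")
  for (it in 1:50) {
    tm <- (tlo + thi) / 2
    fm <- geom$sdf(matrix(c0, n_rays, 3, byrow = TRUE) + tm * dirs)
    neg <- fm < 0
    tlo[neg] <- tm[neg]; thi[!neg] <- tm[!neg]
  }
  2 * mean((tlo + thi) / 2)
}

#' Measure anatomical parameters from a built geometry
#'
#' Recovers the headline anatomy from a `cab_geometry`: branch angles from
#' the centerline tangent directions at the apex, and diameters from lumen
#' cross-sections (the CCA inlet diameter by linear extrapolation of two
#' stations to the inlet plane; the ICA diameter downstream of the sinus,
#' per the diameter-ratio convention; the maximum sinus diameter by a
#' bounded 1D search over the sinus segment).
#'
#' @param geom a `cab_geometry` from [build_geometry()].
#' @return list with `cca_inlet_diameter`, `ica_cca_diameter_ratio`,
#'   `ica_branch_angle`, `eca_branch_angle`, `total_branch_angle`,
#'   `sinus_max_diameter`, `eca_diameter` (m / degrees).
#' @export
measure_geometry <- function(geom) {
  stopifnot(inherits(geom, "cab_geometry"))
  if (is.null(geom$surface$labels)) stop("geometry has unlabeled branches")
  angle_of <- function(d) acos(sum(d * geom$branch_dirs$cca)) * 180 / pi
  tang <- function(branch) {
    cl <- geom$centerlines[[branch]]
    v <- as.numeric(cl[2, 1:3]) - as.numeric(cl[1, 1:3])
    l <- sqrt(sum(v^2))
    if (l == 0) stop("degenerate centerline for branch ", branch)
    v / l
  }
  ia <- angle_of(tang("ica")); ea <- angle_of(tang("eca"))

  # CCA inlet: extrapolate two interior stations to s = 0 (linear taper)
  Lc <- geom$branch_lengths$cca
  s1 <- 0.15 * Lc; s2 <- 0.45 * Lc
  d1 <- .section_diameter(geom, "cca", s1)
  d2 <- .section_diameter(geom, "cca", s2)
  d_in <- d1 - (d2 - d1) / (s2 - s1) * s1

  # ICA downstream of the sinus (constant section before the exit cap)
  seg <- geom$sinus_segment
  s_down <- seg[2] + 0.5 * (geom$branch_lengths$ica - seg[2])
  d_ica <- .section_diameter(geom, "ica", s_down)

  # sinus maximum by bounded search around the bulge center (the sections
  # near the sinus entry open into the bifurcation junction)
  ds <- function(s) .section_diameter(geom, "ica", s)
  mid <- mean(seg); Ls <- diff(seg)
  opt <- stats::optimize(ds, lower = mid - 0.3 * Ls, upper = mid + 0.3 * Ls,
                         maximum = TRUE, tol = 1e-10)
  d_sin <- max(opt$objective, ds(mid))

  s_eca <- 0.5 * (geom$sinus_segment[1] + geom$branch_lengths$eca)
  d_eca <- .section_diameter(geom, "eca", max(s_eca, 0.6 * geom$branch_lengths$eca))

  list(cca_inlet_diameter = d_in,
       ica_cca_diameter_ratio = d_ica / d_in,
       ica_branch_angle = ia,
       eca_branch_angle = ea,
       total_branch_angle = ia + ea,
       sinus_max_diameter = d_sin,
       eca_diameter = d_eca)
}

#' Sinus-anchored coordinate frame
#'
#' The translated and rotated frame all downstream kinematics are expressed
#' in: origin at the bifurcation apex, axial unit vector along the ICA sinus
#' center axis (the downstream direction), and a right-handed orthonormal
#' in-plane pair. The axial coordinate of a point in this frame is xi.
#'
#' @param geom a `cab_geometry`, or a list with `apex` and `branch_dirs$ica`.
#' @return Object of class `sinus_frame` with fields `origin`, `axial`,
#'   `e2`, `e3` (orthonormal to 1e-12).
#' @export
sinus_frame <- function(geom) {
  origin <- geom$apex
  ax <- geom$branch_dirs$ica
  l <- sqrt(sum(ax^2))
  if (!is.finite(l) || l == 0) stop("degenerate ICA centerline: zero-length axial direction")
  ax <- ax / l
  zv <- c(0, 0, 1)
  e2 <- c(zv[2] * ax[3] - zv[3] * ax[2], zv[3] * ax[1] - zv[1] * ax[3],
          zv[1] * ax[2] - zv[2] * ax[1])
  l2 <- sqrt(sum(e2^2))
  if (l2 < 1e-12) { # axial parallel to z: fall back to x as reference
    e2 <- c(1, 0, 0) - ax * ax[1]; l2 <- sqrt(sum(e2^2))
  }
  e2 <- e2 / l2
  e3 <- c(ax[2] * e2[3] - ax[3] * e2[2], ax[3] * e2[1] - ax[1] * e2[3],
          ax[1] * e2[2] - ax[2] * e2[1])
  structure(list(origin = origin, axial = ax, e2 = e2, e3 = e3),
            class = "sinus_frame")
}

#' Transform world coordinates into the sinus frame
#'
#' @param frame a [sinus_frame()].
#' @param pts N x 3 matrix (or length-3 vector) of world coordinates (m).
#' @return N x 3 matrix of frame coordinates (xi = axial, eta, zeta).
#' @export
to_sinus_frame <- function(frame, pts) {
  stopifnot(inherits(frame, "sinus_frame"))
  pts <- if (is.null(dim(pts))) matrix(pts, 1) else as.matrix(pts)
  sweep(pts, 2, frame$origin) %*% cbind(frame$axial, frame$e2, frame$e3)
}

#' Inverse transform from the sinus frame to world coordinates
#'
#' @param frame a [sinus_frame()].
#' @param xi N x 3 matrix of frame coordinates.
#' @return N x 3 matrix of world coordinates.
#' @export
from_sinus_frame <- function(frame, xi) {
  stopifnot(inherits(frame, "sinus_frame"))
  xi <- if (is.null(dim(xi))) matrix(xi, 1) else as.matrix(xi)
  sweep(xi %*% t(cbind(frame$axial, frame$e2, frame$e3)), 2, frame$origin, "+")
}
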