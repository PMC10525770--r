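#' Centerline-perpendicular cross-section plane
#'
#' A sampling plane normal to the local centerline tangent, carrying a
#' Cartesian in-plane grid masked to a disk. Velocity interpolated onto the
#' grid supports the secondary-flow decomposition, in-plane vorticity and
#' area-weighted pressure averages.
#'
#' @param center plane center on the centerline (length 3, m).
#' @param normal plane unit normal = local centerline tangent.
#' @param radius disk radius (m).
#' @param n in-plane grid resolution (n x n).
#' @param index plane label (1 = most upstream).
#' @return Object of class `cross_section_plane` with fields `center`,
#'   `normal`, `e1`, `e2` (orthonormal in-plane basis), `u`, `v` (in-plane
#'   coordinates), `samples` (M x 3 world coordinates of the masked disk
#'   samples), `mask` (n x n logical), `h` (grid spacing), `index`.
#' @export
cross_section_plane <- function(center, normal, radius, n = 25L, index = 1L) {
  stopifnot(radius > 0, n >= 5L)
  normal <- normal / sqrt(sum(normal^2))
  # in-plane basis: e1 in the global x-y plane where possible
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - normal * sum(ref * normal)
  e1 <- e1 / sqrt(sum(e1^2))
  e1 <- c(e1[2] * normal[3] - e1[3] * normal[2],
          e1[3] * normal[1] - e1[1] * normal[3],
          e1[1] * normal[2] - e1[2] * normal[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  uu <- seq(-radius, radius, length.out = n)
  gg <- expand.grid(u = uu, v = uu)
  mask <- matrix(gg$u^2 + gg$v^2 <= radius^2, n, n)
  samples <- matrix(rep(center, each = nrow(gg)), ncol = 3) +
    outer(gg$u, e1) + outer(gg$v, e2)
  structure(list(center = center, normal = normal, e1 = e1, e2 = e2,
                 u = uu, v = uu, samples = samples, mask = mask,
                 h = uu[2] - uu[1], radius = radius, index = index),
            class = "cross_section_plane")
}

#' Planes across the ICA sinus of a built geometry
#'
#' Places `n_planes` planes perpendicular to the ICA centerline, uniformly
#' spaced in arc length across the sinus segment, labeled 1 (most upstream)
#' to `n_planes` (most downstream).
#'
#' @param geom a `cab_geometry` (see [build_geometry()]).
#' @param n_planes number of planes (default 6).
#' @param n in-plane resolution per plane.
#' @param stations optional arc-length stations (m along the ICA centerline)
#'   overriding the uniform placement.
#' @return List of [cross_section_plane()]s.
#' @export
sinus_planes <- function(geom, n_planes = 6L, n = 25L, stations = NULL) {
  stopifnot(inherits(geom, "cab_geometry"))
  seg <- geom$sinus_segment   # c(s_start, s_end) on the ICA centerline
  if (is.null(stations)) {
    stations <- seq(seg[1], seg[2], length.out = n_planes + 2L)[2:(n_planes + 1L)]
  }
  dir <- geom$branch_dirs$ica
  lapply(seq_along(stations), function(i) {
    s <- stations[i]
    cross_section_plane(center = geom$apex + s * dir, normal = dir,
                        radius = geom$radius_fns$ica(s) * 0.98, n = n,
                        index = i)
  })
}

#' Axial/secondary velocity decomposition on cross-section planes
#'
#' Interpolates the snapshot velocity onto each plane and splits it into the
#' axial component `u . n` and the in-plane (secondary) components, with the
#' nondimensional secondary magnitude `u/U` formed with a reference speed `U`
#' (by convention the mean CCA-inlet speed at t/T = 0.27). The decomposition
#' is exactly norm-conserving: `axial^2 + |secondary|^2 = |u|^2`.
#'
#' @param snapshot a [flow_snapshot()] on a structured grid.
#' @param planes list of [cross_section_plane()]s.
#' @param U_ref reference speed (m/s) for `u/U`.
#' @return List of `secondary_field` objects with fields `axial`, `s1`, `s2`
#'   (in-plane components on the e1/e2 basis), `sec_mag`, `u_over_U`,
#'   `vorticity_n` (in-plane vorticity, 1/s), all as masked n x n matrices,
#'   plus the generating `plane` and `U_ref`.
#' @export
slice_and_decompose <- function(snapshot, planes, U_ref) {
  stopifnot(inherits(snapshot, "flow_snapshot"), U_ref > 0)
  if (is.null(snapshot$grid)) stop("secondary-flow slicing needs a structured snapshot")
  lapply(planes, function(pl) {
    uvw <- interp_trilinear(snapshot$grid, snapshot$velocity, pl$samples)
    if (all(is.na(uvw[pl$mask, 1]))) {
      stop("plane ", pl$index, " lies outside the fluid domain")
    }
    n <- length(pl$u)
    shape <- function(x) matrix(x, n, n)
    axial <- shape(drop(uvw %*% pl$normal))
    s1 <- shape(drop(uvw %*% pl$e1))
    s2 <- shape(drop(uvw %*% pl$e2))
    axial[!pl$mask] <- NA; s1[!pl$mask] <- NA; s2[!pl$mask] <- NA
    sec <- sqrt(s1^2 + s2^2)
    # in-plane vorticity d s2/d u - d s1/d v by central differences
    wn <- matrix(NA_real_, n, n)
    h2 <- 2 * pl$h
    wn[2:(n - 1), 2:(n - 1)] <-
      (s2[3:n, 2:(n - 1)] - s2[1:(n - 2), 2:(n - 1)]) / h2 -
      (s1[2:(n - 1), 3:n] - s1[2:(n - 1), 1:(n - 2)]) / h2
    structure(list(axial = axial, s1 = s1, s2 = s2, sec_mag = sec,
                   u_over_U = sec / U_ref, vorticity_n = wn,
                   plane = pl, U_ref = U_ref),
              class = "secondary_field")
  })
}

#' Count counter-rotating vortex pairs on a cross-section plane
#'
#' Thresholds the in-plane vorticity at a fraction `f` of its maximum
#' magnitude, labels connected blobs (8-connectivity), integrates the
#' circulation of each blob, and pairs opposite-signed blobs of comparable
#' strength (`|G1/G2|` in [0.5, 2]) by smallest centroid separation (within
#' one plane diameter). A counter-rotating pair in the Dean-vortex sense is
#' one such matched pair.
#'
#' @param sf a `secondary_field`.
#' @param f vorticity threshold fraction (default 0.2).
#' @return list with `n_pairs`, `pairs` (data.frame: blob ids, circulations,
#'   separation), `blobs` (data.frame: id, circulation, centroid, n_cells).
#' @export
count_vortex_pairs <- function(sf, f = 0.2) {
  stopifnot(inherits(sf, "secondary_field"), f > 0, f < 1)
  wn <- sf$vorticity_n
  mx <- max(abs(wn), na.rm = TRUE)
  empty <- list(n_pairs = 0L,
                pairs = data.frame(id1 = integer(0), id2 = integer(0),
                                   G1 = numeric(0), G2 = numeric(0),
                                   separation = numeric(0)),
                blobs = data.frame(id = integer(0), circulation = numeric(0),
                                   cu = numeric(0), cv = numeric(0),
                                   n_cells = integer(0)))
  if (!is.finite(mx) || mx == 0) return(empty)
  act <- !is.na(wn) & abs(wn) > f * mx
  lab <- .label_blobs_2d(act & wn > 0)
  labn <- .label_blobs_2d(act & wn < 0)
  nb_pos <- max(lab, 0)
  labn[labn > 0] <- labn[labn > 0] + nb_pos
  lab[labn > 0] <- labn[labn > 0]
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0L) return(empty)
  dA <- sf$plane$h^2
  blobs <- do.call(rbind, lapply(ids, function(id) {
    cells <- which(lab == id, arr.ind = TRUE)
    data.frame(id = id,
               circulation = sum(wn[lab == id]) * dA,
               cu = mean(sf$plane$u[cells[, 1]]),
               cv = mean(sf$plane$v[cells[, 2]]),
               n_cells = nrow(cells))
  }))
  # candidate pairings: opposite sign, comparable strength, close enough
  cand <- expand.grid(i = seq_len(nrow(blobs)), j = seq_len(nrow(blobs)))
  cand <- cand[cand$i < cand$j, , drop = FALSE]
  if (nrow(cand)) {
    G1 <- blobs$circulation[cand$i]; G2 <- blobs$circulation[cand$j]
    rat <- abs(G1 / G2)
    cand <- cand[sign(G1) != sign(G2) & rat >= 0.5 & rat <= 2, , drop = FALSE]
  }
  if (nrow(cand)) {
    cand$sep <- sqrt((blobs$cu[cand$i] - blobs$cu[cand$j])^2 +
                     (blobs$cv[cand$i] - blobs$cv[cand$j])^2)
    cand <- cand[cand$sep < 2 * sf$plane$radius, , drop = FALSE]
    cand <- cand[order(cand$sep), , drop = FALSE]
  }
  used <- logical(nrow(blobs))
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      id1 = blobs$id[i], id2 = blobs$id[j],
      G1 = blobs$circulation[i], G2 = blobs$circulation[j],
      separation = cand$sep[r])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else empty$pairs
  list(n_pairs = nrow(pairs), pairs = pairs, blobs = blobs)
}

# 4/8-connectivity labeling of a logical matrix via igraph components
.label_blobs_2d <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  lab <- matrix(0L, n1, n2)
  idx <- which(m)
  if (length(idx) == 0L) return(lab)
  i <- (idx - 1L) %% n1; j <- (idx - 1L) %/% n1
  inset <- m
  efrom <- integer(0); eto <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    ok <- i2 >= 0 & i2 < n1 & j2 >= 0 & j2 < n2
    nb <- i2 + j2 * n1 + 1L
    ok[ok] <- inset[nb[ok]]
    efrom <- c(efrom, idx[ok]); eto <- c(eto, nb[ok])
  }
  comp <- .components_from_edges(idx, efrom, eto)
  for (k in seq_along(comp)) lab[comp[[k]]] <- k
  lab
}
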