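#' Connected vortex regions below a lambda2 threshold
#'
#' Extracts the connected components of the point set `{lambda2 < threshold}`.
#' On structured grids, voxel 26-connectivity is used; on unstructured point
#' sets, an adjacency list must be supplied (mesh edge-connectivity).
#' Components smaller than `min_size` points are discarded as numerical
#' noise; the survivors are returned sorted by volume (largest first).
#'
#' @param field a [lambda2_field()].
#' @param threshold lambda2 iso-value, must be <= 0. The string `"auto"`
#'   selects `-5%` of the 99th percentile of `|lambda2|` (scale-free default;
#'   the chosen value is recorded on each region).
#' @param min_size minimum member count per region.
#' @param adjacency list of integer neighbor vectors (unstructured only).
#' @return List of `vortex_region` objects; each has `id`, `members` (point
#'   indices), `n`, `volume` (m^3; voxel count times cell volume on uniform
#'   structured grids), `centroid`, `bbox` (2 x 3), `min_lambda2`, `phase`,
#'   `threshold`. Empty list when nothing is below threshold.
#' @export
extract_vortex_regions <- function(field, threshold = "auto", min_size = 10L,
                                   adjacency = NULL) {
  stopifnot(inherits(field, "lambda2_field"))
  if (identical(threshold, "auto")) {
    threshold <- -0.05 * stats::quantile(abs(field$lambda2), 0.99, names = FALSE)
  }
  if (threshold > 0) stop("lambda2 threshold must be <= 0")
  members_all <- which(field$lambda2 < threshold)
  if (length(members_all) == 0L) return(list())

  comp <- if (!is.null(field$grid)) {
    .components_structured(members_all, field$grid$dims)
  } else {
    if (is.null(adjacency)) {
      stop("unstructured lambda2 field needs an `adjacency` list")
    }
    .components_adjacency(members_all, adjacency)
  }

  cellvol <- if (!is.null(field$grid)) {
    g <- field$grid
    mean(diff(g$x)) * mean(diff(g$y)) * mean(diff(g$z))
  } else {
    NA_real_
  }

  regs <- lapply(seq_along(comp), function(i) {
    idx <- comp[[i]]
    pts <- field$points[idx, , drop = FALSE]
    structure(list(
      id = i, members = idx, n = length(idx),
      volume = if (is.na(cellvol)) NA_real_ else length(idx) * cellvol,
      centroid = colMeans(pts),
      bbox = rbind(apply(pts, 2, min), apply(pts, 2, max)),
      min_lambda2 = min(field$lambda2[idx]),
      points = pts,
      phase = NA_real_, threshold = threshold),
      class = "vortex_region")
  })
  regs <- regs[regs_sizes <- vapply(regs, function(r) r$n, 0L) >= min_size]
  ord <- order(vapply(regs, function(r) -r$n, 0))
  regs <- regs[ord]
  for (i in seq_along(regs)) regs[[i]]$id <- i
  regs
}

# connected components of voxel subset under 26-connectivity via igraph
.components_structured <- function(members, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  inset <- logical(prod(dims)); inset[members] <- TRUE
  k <- members - 1L
  ix <- k %% nx; iy <- (k %/% nx) %% ny; iz <- k %/% (nx * ny)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)), , drop = FALSE]
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    jx <- ix + offs[r, 1]; jy <- iy + offs[r, 2]; jz <- iz + offs[r, 3]
    ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
    nb <- jx + jy * nx + jz * nx * ny + 1L
    ok[ok] <- inset[nb[ok]]
    efrom <- c(efrom, members[ok]); eto <- c(eto, nb[ok])
  }
  .components_from_edges(members, efrom, eto)
}

.components_adjacency <- function(members, adjacency) {
  inset <- logical(max(members, vapply(adjacency, function(x) if (length(x)) max(x) else 0L, 0L)))
  inset[members] <- TRUE
  efrom <- integer(0); eto <- integer(0)
  for (i in members) {
    nb <- adjacency[[i]]
    nb <- nb[nb > i & inset[nb]]
    if (length(nb)) { efrom <- c(efrom, rep(i, length(nb))); eto <- c(eto, nb) }
  }
  .components_from_edges(members, efrom, eto)
}

.components_from_edges <- function(members, efrom, eto) {
  vid <- match(members, members)   # identity, members are the vertex universe
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(efrom, members), to = match(eto, members)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(members)))
  cm <- igraph::components(g)$membership
  # igraph vertex order follows the vertices frame, names are 1..m as character
  cm <- cm[order(as.integer(names(cm)))]
  split(members, cm)
}

#' @export
print.vortex_region <- function(x, ...) {
  cat(sprintf("vortex region %d: %d points, min lambda2 %.3g, centroid (%.3g, %.3g, %.3g)\n",
              x$id, x$n, x$min_lambda2, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Presence windows of tracked vortex regions over a cycle
#'
#' Runs the gradient -> lambda2 -> region-extraction pipeline on every
#' snapshot of a series at one constant threshold, matches regions frame to
#' frame, and reports for each track the first and last phase at which it
#' exists. Matching is by maximum bounding-box overlap volume, tie-broken by
#' smallest centroid distance and then lowest region id (deterministic).
#'
#' @param series a [flow_series()].
#' @param threshold constant lambda2 iso-value (or `"auto"`, resolved once
#'   from the pooled series so it is identical across phases).
#' @param min_size minimum region size (points).
#' @param max_gap a track survives up to this many consecutive absent frames.
#' @param adjacency passed through for unstructured snapshots.
#' @return data.frame with columns `track`, `t_start`, `t_end`, `lifespan`
#'   (all in t/T units), `n_frames`, `max_points`; the per-frame region lists
#'   are attached as attribute `"frames"` and the resolved threshold as
#'   attribute `"threshold"`.
#' @export
region_presence_window <- function(series, threshold = "auto", min_size = 10L,
                                   max_gap = 0L, adjacency = NULL) {
  stopifnot(inherits(series, "flow_series"))
  frames <- lapply(series$snapshots, function(s) {
    lambda2_field(velocity_gradient(s))
  })
  if (identical(threshold, "auto")) {
    pooled <- unlist(lapply(frames, function(f) abs(f$lambda2)))
    threshold <- -0.05 * stats::quantile(pooled, 0.99, names = FALSE)
  }
  regs <- lapply(seq_along(frames), function(i) {
    r <- extract_vortex_regions(frames[[i]], threshold, min_size, adjacency)
    for (j in seq_along(r)) r[[j]]$phase <- series$phases[i]
    r
  })

  # frame-to-frame matching into tracks
  tracks <- list()      # each: list(last_region, start, end, frames, gap, maxn)
  for (i in seq_along(regs)) {
    cur <- regs[[i]]
    assigned <- rep(FALSE, length(cur))
    live <- which(vapply(tracks, function(tr) tr$gap <= max_gap, TRUE))
    for (ti in live) {
      tr <- tracks[[ti]]
      if (length(cur) == 0L) { tracks[[ti]]$gap <- tr$gap + 1L; next }
      score <- vapply(cur, function(r) .bbox_overlap(tr$last$bbox, r$bbox), 0)
      score[assigned] <- -Inf
      if (all(score <= 0)) { tracks[[ti]]$gap <- tr$gap + 1L; next }
      best <- which(score == max(score))
      if (length(best) > 1L) {
        cd <- vapply(cur[best], function(r) sum((r$centroid - tr$last$centroid)^2), 0)
        best <- best[cd == min(cd)]
        best <- best[1L]          # lowest id last
      }
      assigned[best] <- TRUE
      tracks[[ti]]$last <- cur[[best]]
      tracks[[ti]]$end <- series$phases[i]
      tracks[[ti]]$frames <- tracks[[ti]]$frames + 1L
      tracks[[ti]]$gap <- 0L
      tracks[[ti]]$maxn <- max(tracks[[ti]]$maxn, cur[[best]]$n)
    }
    for (j in which(!assigned)) {
      tracks[[length(tracks) + 1L]] <- list(
        last = cur[[j]], start = series$phases[i], end = series$phases[i],
        frames = 1L, gap = 0L, maxn = cur[[j]]$n)
    }
  }

  out <- data.frame(
    track = seq_along(tracks),
    t_start = vapply(tracks, function(tr) tr$start, 0),
    t_end = vapply(tracks, function(tr) tr$end, 0),
    n_frames = vapply(tracks, function(tr) tr$frames, 0L),
    max_points = vapply(tracks, function(tr) tr$maxn, 0L))
  out$lifespan <- out$t_end - out$t_start
  out <- out[order(-out$n_frames, out$t_start), c("track", "t_start", "t_end",
                                                  "lifespan", "n_frames", "max_points")]
  rownames(out) <- NULL
  attr(out, "frames") <- regs
  attr(out, "threshold") <- threshold
  out
}

.bbox_overlap <- function(b1, b2) {
  lo <- pmax(b1[1, ], b2[1, ]); hi <- pmin(b1[2, ], b2[2, ])
  if (any(hi < lo)) return(0)
  prod(hi - lo)
}
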