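#' Structured box grid
#'
#' A tensor-product grid of points used by the finite-difference paths
#' (velocity gradients, connected components on voxels). Point ordering is
#' x-fastest (`expand.grid` order), and the dimensions travel with the point
#' matrix so downstream code can reshape per-point arrays back into 3D.
#'
#' @param x,y,z strictly increasing coordinate vectors (m). `y`/`z` default
#'   to `x`.
#' @return An object of class `structured_grid` with fields `x`, `y`, `z`,
#'   `dims`, `points` (N x 3 matrix).
#' @export
structured_grid <- function(x, y = x, z = x) {
  stopifnot(all(diff(x) > 0), all(diff(y) > 0), all(diff(z) > 0),
            length(x) >= 2, length(y) >= 2, length(z) >= 2)
  pts <- as.matrix(expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  structure(list(x = x, y = y, z = z,
                 dims = c(length(x), length(y), length(z)),
                 points = pts),
            class = "structured_grid")
}

#' @export
print.structured_grid <- function(x, ...) {
  cat(sprintf("structured grid %d x %d x %d (%d points)\n",
              x$dims[1], x$dims[2], x$dims[3], nrow(x$points)))
  invisible(x)
}

# coerce either a structured_grid or a plain N x 3 matrix to points
.grid_points <- function(grid) {
  if (inherits(grid, "structured_grid")) return(grid$points)
  m <- as.matrix(grid)
  stopifnot(ncol(m) == 3)
  m
}

.grid_dims <- function(grid) {
  if (inherits(grid, "structured_grid")) grid$dims else NULL
}

#' Trilinear interpolation on a structured grid
#'
#' @param grid a [structured_grid()].
#' @param values numeric vector (length = number of grid points) or matrix
#'   (one column per component), in grid point order.
#' @param xyz N x 3 matrix of query points; points outside the box return NA.
#' @return Interpolated values, vector or matrix matching `values`.
#' @export
interp_trilinear <- function(grid, values, xyz) {
  stopifnot(inherits(grid, "structured_grid"))
  xyz <- as.matrix(xyz)
  vals <- as.matrix(values)
  stopifnot(nrow(vals) == nrow(grid$points))
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]

  loc1 <- function(q, g) {
    i <- findInterval(q, g, rightmost.closed = TRUE)
    i[q < g[1] | q > g[length(g)]] <- NA_integer_
    pmin(pmax(i, 1L), length(g) - 1L)
  }
  ix <- loc1(xyz[, 1], grid$x); iy <- loc1(xyz[, 2], grid$y); iz <- loc1(xyz[, 3], grid$z)
  fx <- (xyz[, 1] - grid$x[ix]) / (grid$x[ix + 1L] - grid$x[ix])
  fy <- (xyz[, 2] - grid$y[iy]) / (grid$y[iy + 1L] - grid$y[iy])
  fz <- (xyz[, 3] - grid$z[iz]) / (grid$z[iz + 1L] - grid$z[iz])

  lin <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  out <- matrix(NA_real_, nrow(xyz), ncol(vals))
  ok <- !is.na(ix) & !is.na(iy) & !is.na(iz)
  if (any(ok)) {
    for (c in seq_len(ncol(vals))) {
      v <- vals[, c]
      acc <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        w <- (if (dx) fx[ok] else 1 - fx[ok]) *
             (if (dy) fy[ok] else 1 - fy[ok]) *
             (if (dz) fz[ok] else 1 - fz[ok])
        acc <- acc + w * v[lin(ix[ok] + dx, iy[ok] + dy, iz[ok] + dz)]
      }
      out[ok, c] <- acc
    }
  }
  if (is.null(dim(values))) drop(out) else out
}
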