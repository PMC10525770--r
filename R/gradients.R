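#' Velocity-gradient tensor field
#'
#' Computes the 3x3 velocity-gradient tensor `J` at every point of a snapshot
#' and its symmetric/antisymmetric split: the strain-rate tensor
#' `S = (J + J^T)/2` and the rotation-rate tensor `O = (J - J^T)/2`.
#'
#' On structured grids, second-order central differences are used in the
#' interior with second-order one-sided stencils at the box boundary. On
#' unstructured point sets, a distance-weighted least-squares fit over each
#' point's neighbors is used; the fit is exact for affine velocity fields.
#'
#' @param snapshot a [flow_snapshot()].
#' @param neighbors for unstructured snapshots, a list of integer neighbor
#'   index vectors (>= 4 non-coplanar neighbors per point). If NULL and the
#'   snapshot is unstructured, k-nearest neighbors are built by brute force
#'   (suitable only for small point sets).
#' @param k neighbors per point for the brute-force kNN fallback.
#' @return Object of class `gradient_field` with fields `J` (N x 9, row-major
#'   rows of the tensor), `S` (N x 6: xx, yy, zz, xy, xz, yz), `W` (N x 3:
#'   the xy, xz, yz entries of the rotation tensor), `points`, `grid`.
#' @export
velocity_gradient <- function(snapshot, neighbors = NULL, k = 12L) {
  stopifnot(inherits(snapshot, "flow_snapshot"))
  J <- if (!is.null(snapshot$grid)) {
    .grad_structured(snapshot)
  } else {
    .grad_lsq(snapshot$points, snapshot$velocity, neighbors, k)
  }
  # symmetric part (6 comps) and antisymmetric part (3 comps)
  S <- cbind(J[, 1], J[, 5], J[, 9],
             (J[, 2] + J[, 4]) / 2, (J[, 3] + J[, 7]) / 2, (J[, 6] + J[, 8]) / 2)
  W <- cbind((J[, 2] - J[, 4]) / 2, (J[, 3] - J[, 7]) / 2, (J[, 6] - J[, 8]) / 2)
  structure(list(J = J, S = S, W = W,
                 points = snapshot$points, grid = snapshot$grid),
            class = "gradient_field")
}

# central differences along one axis of a 3D array, one-sided at the ends
.diff_axis <- function(arr, coords, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 3) stop("need >= 3 points per axis for finite differences")
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  out <- matrix(0, n, ncol(m))
  h <- diff(coords)
  # interior: central over possibly nonuniform spacing
  out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (coords[3:n] - coords[1:(n - 2)])
  uniform <- diff(range(h)) < 1e-9 * mean(h)
  if (uniform) {
    h1 <- h[1]
    out[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * h1)
    out[n, ] <- (3 * m[n, ] - 4 * m[n - 1, ] + m[n - 2, ]) / (2 * h1)
  } else {
    out[1, ] <- (m[2, ] - m[1, ]) / h[1]
    out[n, ] <- (m[n, ] - m[n - 1, ]) / h[n - 1]
  }
  aperm(array(out, dim(a)), order(perm))
}

.grad_structured <- function(snapshot) {
  g <- snapshot$grid
  d <- g$dims
  J <- matrix(0, nrow(snapshot$points), 9L)
  coords <- list(g$x, g$y, g$z)
  for (comp in 1:3) {
    arr <- array(snapshot$velocity[, comp], d)
    for (axis in 1:3) {
      J[, (comp - 1L) * 3L + axis] <- as.vector(.diff_axis(arr, coords[[axis]], axis))
    }
  }
  J
}

.knn_brute <- function(pts, k) {
  n <- nrow(pts)
  if (n > 5000L) {
    warning("brute-force kNN on ", n, " points; pass `neighbors` for large sets")
  }
  k <- min(k, n - 1L)
  lapply(seq_len(n), function(i) {
    d2 <- rowSums(sweep(pts, 2, pts[i, ])^2)
    order(d2)[2:(k + 1L)]
  })
}

.grad_lsq <- function(pts, vel, neighbors, k) {
  if (is.null(neighbors)) neighbors <- .knn_brute(pts, k)
  n <- nrow(pts)
  J <- matrix(0, n, 9L)
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (length(nb) < 3L) stop("point ", i, ": fewer than 3 neighbors")
    A <- sweep(pts[nb, , drop = FALSE], 2, pts[i, ])
    b <- sweep(vel[nb, , drop = FALSE], 2, vel[i, ])
    w <- 1 / pmax(rowSums(A^2), .Machine$double.eps)
    AtWA <- crossprod(A * w, A)
    if (rcond(AtWA) < 1e-12) {
      stop("point ", i, ": neighborhood is (near-)coplanar, gradient fit singular")
    }
    G <- solve(AtWA, crossprod(A * w, b))   # 3 x 3, G[k, comp] = d u_comp / d x_k
    J[i, ] <- as.vector(G)                  # row-major rows of J = columns of G
  }
  J
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("gradient field at %d points%s\n", nrow(x$J),
              if (is.null(x$grid)) " (least-squares)" else " (finite-difference)"))
  invisible(x)
}
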