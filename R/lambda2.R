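#' Lambda2 vortex-identification field
#'
#' Forms the symmetric tensor `S^2 + O^2` from a [velocity_gradient()] field
#' and computes its (real) eigenvalues at every point, sorted
#' `lambda1 >= lambda2 >= lambda3`. A point belongs to a vortex core when two
#' eigenvalues are negative, i.e. when `lambda2 < 0`.
#'
#' The per-point eigensolve uses the closed-form trigonometric method for
#' symmetric 3x3 matrices (vectorized over all points); the tensor is exactly
#' symmetric by construction so all eigenvalues are real.
#'
#' @param grad a `gradient_field`.
#' @return Object of class `lambda2_field` with fields `lambda` (N x 3 sorted
#'   descending), `lambda2` (convenience column), `M` (N x 6 symmetric tensor
#'   storage xx, yy, zz, xy, xz, yz), `points`, `grid`.
#' @export
lambda2_field <- function(grad) {
  stopifnot(inherits(grad, "gradient_field"))
  S <- grad$S; W <- grad$W
  if (any(!is.finite(S)) || any(!is.finite(W))) {
    bad <- which(!stats::complete.cases(cbind(S, W)))[1]
    stop("non-finite velocity-gradient tensor at point ", bad)
  }
  s11 <- S[, 1]; s22 <- S[, 2]; s33 <- S[, 3]
  s12 <- S[, 4]; s13 <- S[, 5]; s23 <- S[, 6]
  a <- W[, 1]; b <- W[, 2]; c <- W[, 3]    # O_xy, O_xz, O_yz

  # M = S^2 + O^2, symmetric
  m11 <- s11^2 + s12^2 + s13^2 - a^2 - b^2
  m22 <- s12^2 + s22^2 + s23^2 - a^2 - c^2
  m33 <- s13^2 + s23^2 + s33^2 - b^2 - c^2
  m12 <- s11 * s12 + s12 * s22 + s13 * s23 - b * c
  m13 <- s11 * s13 + s12 * s23 + s13 * s33 + a * c
  m23 <- s12 * s13 + s22 * s23 + s23 * s33 - a * b

  lam <- .eig3_sym(m11, m22, m33, m12, m13, m23)
  dimnames(lam) <- NULL
  structure(list(lambda = lam, lambda2 = unname(lam[, 2]),
                 M = cbind(m11, m22, m33, m12, m13, m23),
                 points = grad$points, grid = grad$grid),
            class = "lambda2_field")
}

# vectorized eigenvalues of symmetric 3x3 matrices by cyclic Jacobi sweeps
# (quadratic convergence; near machine precision after a handful of sweeps,
# which the closed-form trigonometric method cannot deliver for the
# near-degenerate pairs that rigid-body rotation produces), sorted descending
.eig3_sym <- function(m11, m22, m33, m12, m13, m23) {
  for (sweep in 1:6) {
    off <- pmax(abs(m12), abs(m13), abs(m23))
    scale <- pmax(abs(m11), abs(m22), abs(m33), off)
    if (all(off <= 1e-16 * scale)) break
    # pivot (1,2)
    act <- m12 != 0
    if (any(act)) {
      tau <- (m22[act] - m11[act]) / (2 * m12[act])
      t <- sign(tau) / (abs(tau) + sqrt(1 + tau^2))
      t[tau == 0] <- 1
      cs <- 1 / sqrt(1 + t^2); sn <- t * cs
      h <- t * m12[act]
      m11[act] <- m11[act] - h; m22[act] <- m22[act] + h; m12[act] <- 0
      a13 <- m13[act]; a23 <- m23[act]
      m13[act] <- cs * a13 - sn * a23; m23[act] <- sn * a13 + cs * a23
    }
    # pivot (1,3)
    act <- m13 != 0
    if (any(act)) {
      tau <- (m33[act] - m11[act]) / (2 * m13[act])
      t <- sign(tau) / (abs(tau) + sqrt(1 + tau^2))
      t[tau == 0] <- 1
      cs <- 1 / sqrt(1 + t^2); sn <- t * cs
      h <- t * m13[act]
      m11[act] <- m11[act] - h; m33[act] <- m33[act] + h; m13[act] <- 0
      a12 <- m12[act]; a23 <- m23[act]
      m12[act] <- cs * a12 - sn * a23; m23[act] <- sn * a12 + cs * a23
    }
    # pivot (2,3)
    act <- m23 != 0
    if (any(act)) {
      tau <- (m33[act] - m22[act]) / (2 * m23[act])
      t <- sign(tau) / (abs(tau) + sqrt(1 + tau^2))
      t[tau == 0] <- 1
      cs <- 1 / sqrt(1 + t^2); sn <- t * cs
      h <- t * m23[act]
      m22[act] <- m22[act] - h; m33[act] <- m33[act] + h; m23[act] <- 0
      a12 <- m12[act]; a13 <- m13[act]
      m12[act] <- cs * a12 - sn * a13; m13[act] <- sn * a12 + cs * a13
    }
  }
  lam <- cbind(m11, m22, m33, deparse.level = 0)
  # sort each row descending (3 columns: explicit min/mid/max)
  hi <- pmax(lam[, 1], lam[, 2], lam[, 3])
  lo <- pmin(lam[, 1], lam[, 2], lam[, 3])
  cbind(hi, lam[, 1] + lam[, 2] + lam[, 3] - hi - lo, lo, deparse.level = 0)
}

#' @export
print.lambda2_field <- function(x, ...) {
  cat(sprintf("lambda2 field at %d points: lambda2 in [%.3g, %.3g], %d points < 0\n",
              length(x$lambda2), min(x$lambda2), max(x$lambda2),
              sum(x$lambda2 < 0)))
  invisible(x)
}
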