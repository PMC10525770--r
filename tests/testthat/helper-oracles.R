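# Independent oracles and small fixture builders shared across tests.

# per-point eigenvalues of S^2 + O^2 via base R eigen(), sorted descending
eigen_lambda_oracle <- function(grad) {
  n <- nrow(grad$S)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    S <- matrix(c(grad$S[i, 1], grad$S[i, 4], grad$S[i, 5],
                  grad$S[i, 4], grad$S[i, 2], grad$S[i, 6],
                  grad$S[i, 5], grad$S[i, 6], grad$S[i, 3]), 3, 3)
    W <- matrix(c(0, -grad$W[i, 1], -grad$W[i, 2],
                  grad$W[i, 1], 0, -grad$W[i, 3],
                  grad$W[i, 2], grad$W[i, 3], 0), 3, 3)
    M <- S %*% S + W %*% W
    out[i, ] <- sort(eigen((M + t(M)) / 2, symmetric = TRUE,
                           only.values = TRUE)$values, decreasing = TRUE)
  }
  out
}

# brute-force flood fill (BFS, 26-connectivity) over voxel members
flood_fill_oracle <- function(members, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  inset <- logical(prod(dims)); inset[members] <- TRUE
  seen <- logical(prod(dims))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  comps <- list()
  for (seed in members) {
    if (seen[seed]) next
    queue <- seed; seen[seed] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      k <- v - 1L
      i <- k %% nx; j <- (k %/% nx) %% ny; l <- k %/% (nx * ny)
      for (r in seq_len(nrow(offs))) {
        i2 <- i + offs[r, 1]; j2 <- j + offs[r, 2]; l2 <- l + offs[r, 3]
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || l2 < 0 || l2 >= nz) next
        nb <- i2 + j2 * nx + l2 * nx * ny + 1L
        if (inset[nb] && !seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(unname(comp))
  }
  comps
}

# snapshot with superposed Lamb-Oseen tubes (axes parallel to z)
two_tube_snapshot <- function(grid, centers, Gammas, r_c) {
  pts <- grid$points
  vel <- matrix(0, nrow(pts), 3)
  for (k in seq_along(Gammas)) {
    s <- vortex_tube_field("lamb_oseen", grid, Gamma = Gammas[k], r_c = r_c,
                           axis_point = c(centers[k, ], 0))
    vel <- vel + s$velocity
  }
  flow_snapshot(grid, vel, rep(0, nrow(pts)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
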