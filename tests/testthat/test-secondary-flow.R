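box_grid <- function(n = 17, half = 0.5) {
  structured_grid(seq(-half, half, length.out = n))
}

plane_at <- function(normal = c(1, 0, 0), center = c(0, 0, 0), radius = 0.35,
                     n = 21) {
  cross_section_plane(center, normal, radius, n = n)
}

test_that("pure axial plug flow has zero secondary velocity on all planes", {
  g <- box_grid()
  vel <- matrix(rep(c(0.3, 0, 0), each = nrow(g$points)), ncol = 3)
  s <- flow_snapshot(g, vel, rep(0, nrow(g$points)))
  sf <- slice_and_decompose(s, list(plane_at()), U_ref = 0.3)[[1]]
  expect_lt(max(sf$sec_mag, na.rm = TRUE), 1e-12)
  expect_equal(max(sf$axial, na.rm = TRUE), 0.3, tolerance = 1e-12)
})

test_that("in-plane solid-body rotation has zero axial and sec = omega r", {
  g <- box_grid()
  om <- 2
  s <- vortex_tube_field("rigid_rotation", g, omega = om,
                         axis_dir = c(1, 0, 0))   # rotation about the x-axis
  sf <- slice_and_decompose(s, list(plane_at()), U_ref = 1)[[1]]
  expect_lt(max(abs(sf$axial), na.rm = TRUE), 1e-12)
  uu <- outer(sf$plane$u, rep(1, length(sf$plane$v)))
  vv <- outer(rep(1, length(sf$plane$u)), sf$plane$v)
  r <- sqrt(uu^2 + vv^2)
  ok <- sf$plane$mask
  expect_equal(sf$sec_mag[ok], om * r[ok], tolerance = 1e-10)
})

test_that("tilted uniform flow splits with ratio tan(theta)", {
  g <- box_grid()
  th <- 0.3
  vel <- matrix(rep(c(cos(th), sin(th), 0), each = nrow(g$points)), ncol = 3)
  s <- flow_snapshot(g, vel, rep(0, nrow(g$points)))
  sf <- slice_and_decompose(s, list(plane_at()), U_ref = 1)[[1]]
  ok <- sf$plane$mask
  expect_equal(max(sf$sec_mag[ok] / sf$axial[ok]), tan(th), tolerance = 1e-8)
})

test_that("the decomposition conserves the squared speed to 1e-10", {
  g <- box_grid()
  s <- vortex_tube_field("lamb_oseen", g, Gamma = 0.5, r_c = 0.15,
                         axis_dir = c(0, 1, 1) / sqrt(2))
  pl <- plane_at(normal = c(1, 1, 0) / sqrt(2))
  sf <- slice_and_decompose(s, list(pl), U_ref = 1)[[1]]
  u_interp <- interp_trilinear(g, s$velocity, pl$samples)
  lhs <- sf$axial^2 + sf$s1^2 + sf$s2^2
  rhs <- matrix(rowSums(u_interp^2), nrow(sf$axial))
  ok <- sf$plane$mask & is.finite(lhs)
  expect_lt(max(abs(lhs[ok] - rhs[ok])) / max(rhs[ok]), 1e-10)
})

dean_pair_field <- function(g, Gamma = 1, r_c = 0.12, sep = 0.25) {
  up <- vortex_tube_field("lamb_oseen", g, Gamma = Gamma, r_c = r_c,
                          axis_point = c(0, -sep, 0), axis_dir = c(1, 0, 0))
  dn <- vortex_tube_field("lamb_oseen", g, Gamma = -Gamma, r_c = r_c,
                          axis_point = c(0, sep, 0), axis_dir = c(1, 0, 0))
  flow_snapshot(g, up$velocity + dn$velocity, rep(0, nrow(g$points)))
}

test_that("a mirror-symmetric Dean-like pair is counted as exactly one pair", {
  g <- box_grid(25)
  s <- dean_pair_field(g)
  sf <- slice_and_decompose(s, list(plane_at(radius = 0.45, n = 41)),
                            U_ref = 1)[[1]]
  res <- count_vortex_pairs(sf, f = 0.2)
  expect_identical(res$n_pairs, 1L)
  expect_lt(abs(res$pairs$G1 + res$pairs$G2), 0.01 * abs(res$pairs$G1))
  expect_true(sign(res$pairs$G1) != sign(res$pairs$G2))
})

test_that("a single vortex gives zero pairs and one unpaired blob", {
  g <- box_grid(25)
  s <- vortex_tube_field("lamb_oseen", g, Gamma = 1, r_c = 0.12,
                         axis_dir = c(1, 0, 0))
  sf <- slice_and_decompose(s, list(plane_at(radius = 0.45, n = 41)),
                            U_ref = 1)[[1]]
  res <- count_vortex_pairs(sf, f = 0.2)
  expect_identical(res$n_pairs, 0L)
  expect_identical(nrow(res$blobs), 1L)
})

test_that("two constructed pairs are both found, matching a brute-force pairing", {
  g <- box_grid(29)
  a <- dean_pair_field(g, sep = 0.3)
  b1 <- vortex_tube_field("lamb_oseen", g, Gamma = 0.9, r_c = 0.1,
                          axis_point = c(0, 0, -0.3), axis_dir = c(1, 0, 0))
  b2 <- vortex_tube_field("lamb_oseen", g, Gamma = -0.9, r_c = 0.1,
                          axis_point = c(0, 0, 0.3), axis_dir = c(1, 0, 0))
  s <- flow_snapshot(g, a$velocity + b1$velocity + b2$velocity,
                     rep(0, nrow(g$points)))
  sf <- slice_and_decompose(s, list(plane_at(radius = 0.48, n = 51)),
                            U_ref = 1)[[1]]
  res <- count_vortex_pairs(sf, f = 0.2)
  expect_identical(res$n_pairs, 2L)
  # brute force: enumerate all ways to match opposite-sign blobs
  blobs <- res$blobs
  pos <- which(blobs$circulation > 0); neg <- which(blobs$circulation < 0)
  best <- 0L
  for (perm in list(c(1, 2), c(2, 1))) {
    ok <- 0L
    for (k in seq_along(pos)) {
      i <- pos[k]; j <- neg[perm[k]]
      rat <- abs(blobs$circulation[i] / blobs$circulation[j])
      if (rat >= 0.5 && rat <= 2) ok <- ok + 1L
    }
    best <- max(best, ok)
  }
  expect_identical(res$n_pairs, best)
})

test_that("pair counting is invariant under in-plane rotation of the field", {
  g <- box_grid(25)
  base_centers <- rbind(c(-0.25, 0), c(0.25, 0))
  set.seed(5)
  for (th in runif(10, 0, 2 * pi)) {
    R2 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    cc <- base_centers %*% t(R2)
    up <- vortex_tube_field("lamb_oseen", g, Gamma = 1, r_c = 0.12,
                            axis_point = c(0, cc[1, ]), axis_dir = c(1, 0, 0))
    dn <- vortex_tube_field("lamb_oseen", g, Gamma = -1, r_c = 0.12,
                            axis_point = c(0, cc[2, ]), axis_dir = c(1, 0, 0))
    s <- flow_snapshot(g, up$velocity + dn$velocity, rep(0, nrow(g$points)))
    sf <- slice_and_decompose(s, list(plane_at(radius = 0.45, n = 41)),
                              U_ref = 1)[[1]]
    expect_identical(count_vortex_pairs(sf, f = 0.2)$n_pairs, 1L)
  }
})
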