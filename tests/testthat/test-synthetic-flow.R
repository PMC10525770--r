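unit_fluid <- fluid_properties(nu = 1, rho = 1)   # mu = 1

test_that("Poiseuille snapshot carries the closed-form ground truth", {
  g <- structured_grid(seq(-1, 1, length.out = 9),
                       seq(-0.7, 0.7, length.out = 9),
                       seq(-0.7, 0.7, length.out = 9))
  s <- poiseuille_snapshot(a = 1, U_mean = 0.5, fluid = unit_fluid, grid = g)
  gt <- ground_truth(s)
  expect_equal(gt$wss, 2.0)                       # 4 mu U / a
  expect_lt(gt$dpdx, 0)                           # favorable for U > 0
  expect_equal(gt$dpdx, -8 * 0.5)
  # profile: centerline velocity 2 U_mean, wall velocity 0
  expect_equal(gt$profile(0), 1.0)
  expect_equal(gt$profile(1), 0.0)
  s0 <- poiseuille_snapshot(a = 1, U_mean = 0, fluid = unit_fluid, grid = g)
  expect_true(all(s0$velocity == 0))
})

test_that("points outside the pipe are masked, not an error", {
  g <- structured_grid(seq(-1, 1, length.out = 5),
                       seq(-2, 2, length.out = 9),
                       seq(-2, 2, length.out = 9))
  s <- poiseuille_snapshot(a = 1, U_mean = 0.5, fluid = unit_fluid, grid = g)
  r2 <- s$points[, 2]^2 + s$points[, 3]^2
  expect_true(all(r2 <= 1 + 1e-12))
  expect_lt(nrow(s$points), nrow(g$points))
})

test_that("vortex tube fields match their analytic definitions", {
  g <- structured_grid(seq(-0.5, 0.5, length.out = 11))
  rot <- vortex_tube_field("rigid_rotation", g, omega = 2)
  r <- sqrt(rot$points[, 1]^2 + rot$points[, 2]^2)
  expect_equal(sqrt(rowSums(rot$velocity^2)), 2 * r, tolerance = 1e-12)

  sh <- vortex_tube_field("simple_shear", g, gamma = 3)
  expect_equal(sh$velocity[, 1], 3 * sh$points[, 2])
  expect_true(all(sh$velocity[, 2:3] == 0))

  lo <- vortex_tube_field("lamb_oseen", g, Gamma = 1, r_c = 0.1)
  expect_true(all(is.finite(lo$velocity)))        # axis handled by series limit
  gt <- ground_truth(lo)
  r0 <- c(0.05, 0.1, 0.3)
  expect_equal(gt$u_theta(r0), 1 / (2 * pi * r0) * (1 - exp(-r0^2 / 0.01)),
               tolerance = 1e-10)
  # lambda2 sign change sits at the swirl maximum (~1.12 r_c)
  expect_equal(gt$core_radius_lambda2, 1.1209 * 0.1, tolerance = 1e-3)
})

test_that("Lamb-Oseen pressure is a radial-momentum quadrature with p(Inf) = 0", {
  g <- cbind(seq(0.01, 2, length.out = 50), 0, 0)
  lo <- vortex_tube_field("lamb_oseen", g, Gamma = 1, r_c = 0.1,
                          fluid = unit_fluid)
  p <- lo$pressure
  expect_true(all(diff(p) > 0))                   # dp/dr = rho u^2 / r > 0
  expect_lt(abs(p[length(p)]), 5e-3 * abs(p[1]))  # decays toward 0 far out
  # depth at the first sample: remaining integral of rho u_theta^2 / r
  gt <- ground_truth(lo)
  val <- stats::integrate(function(r) gt$u_theta(r)^2 / r, 0.01, Inf)$value
  expect_equal(p[1], -val, tolerance = 1e-3)
})

test_that("Womersley series reduces to Poiseuille in the zero-frequency limit", {
  wf <- make_waveform()
  wf$coef[-1] <- 0 + 0i                           # steady mode only
  a <- 3.25e-3
  fl <- fluid_properties()
  g <- cbind(0, seq(0, a, length.out = 33), 0)
  ser <- womersley_series(a, wf, fl, g, n_steps = 4)
  pois <- poiseuille_snapshot(a, Re(wf$coef[1]), fl, g, clip = FALSE)
  for (k in 1:4) {
    expect_lt(max(abs(ser$snapshots[[k]]$velocity - pois$velocity)), 1e-10)
  }
})

test_that("Womersley number matches the physiological carotid value", {
  expect_equal(womersley_alpha(3.25e-3, 1, 6.95e-7), 9.77, tolerance = 1e-3)
})

test_that("cycle-mean analytic wall shear equals TAWSS of the shear trace", {
  wf <- make_waveform()
  a <- 3.25e-3; fl <- fluid_properties()
  ser <- womersley_series(a, wf, fl, cbind(0, a / 2, 0), n_steps = 200)
  gt <- ground_truth(ser)
  tawss_series <- mean(abs(gt$tau_wall_series))
  dense <- stats::integrate(function(t) abs(gt$tau_wall(t)), 0, 1,
                            subdivisions = 2000, rel.tol = 1e-10)$value
  expect_equal(tawss_series, dense, tolerance = 5e-3)
})

test_that("generated fields are numerically divergence-free", {
  g <- structured_grid(seq(-0.4, 0.4, length.out = 21))
  div_of <- function(snap) {
    J <- velocity_gradient(snap)$J
    max(abs(J[, 1] + J[, 5] + J[, 9]))
  }
  h <- 0.04
  # exact for polynomial fields (central differences on quadratics)
  pois <- poiseuille_snapshot(1, 0.5, unit_fluid, g, clip = FALSE)
  expect_lt(div_of(pois), 1e-6 * max(abs(pois$velocity)) / h)
  rot <- vortex_tube_field("rigid_rotation", g, omega = 2)
  expect_lt(div_of(rot), 1e-6 * max(abs(rot$velocity)) / h)
  sh <- vortex_tube_field("simple_shear", g, gamma = 1)
  expect_lt(div_of(sh), 1e-12)
  # smooth non-polynomial fields: discretization-limited, must shrink with h
  lo1 <- vortex_tube_field("lamb_oseen", g, Gamma = 1, r_c = 0.2)
  g2 <- structured_grid(seq(-0.4, 0.4, length.out = 41))
  lo2 <- vortex_tube_field("lamb_oseen", g2, Gamma = 1, r_c = 0.2)
  expect_lt(div_of(lo2), 0.35 * div_of(lo1))      # ~2nd-order decay
})

test_that("moving pressure-minimum series attaches its exact trajectory", {
  g <- structured_grid(seq(0, 0.1, length.out = 21),
                       seq(-0.02, 0.02, length.out = 9),
                       seq(-0.02, 0.02, length.out = 9))
  traj <- function(t) c(0.02 + 0.05 * t, 0, 0)
  ser <- moving_min_series(traj, g, depth = 50, width = 5e-3, n_steps = 20,
                           velocity_fn = function(t) c(0.05, 0, 0))
  gt <- ground_truth(ser)
  expect_equal(gt$positions[, 1], 0.02 + 0.05 * gt$times)
  expect_equal(gt$velocity_fn(0.3), c(0.05, 0, 0))
  # stationary well: constant truth by construction
  ser0 <- moving_min_series(function(t) c(0.05, 0, 0), g, n_steps = 8)
  expect_true(all(apply(ground_truth(ser0)$positions, 2, function(x) diff(range(x))) == 0))
  # well leaving the grid is an error
  expect_error(moving_min_series(function(t) c(0.02 + 0.2 * t, 0, 0), g),
               "exits the grid")
})

test_that("periodic series close up: frame n is one step before frame 0", {
  g <- structured_grid(seq(0, 0.1, length.out = 6),
                       seq(-0.02, 0.02, length.out = 4),
                       seq(-0.02, 0.02, length.out = 4))
  ser <- moving_min_series(function(t) c(0.05, 0, 0), g, n_steps = 10,
                           T_period = 1)
  expect_equal(length(ser), 10)
  expect_equal(ser$dt * 10, 1)
  expect_equal(ser$phases, (0:9) / 10)
})
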