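local_frame <- sinus_frame(list(apex = c(0, 0, 0),
                                brandirs = NULL,
                                branch_dirs = list(ica = c(1, 0, 0))))

tracking_grid <- function(n = 21) {
  structured_grid(seq(0, 0.1, length.out = n),
                  seq(-0.02, 0.02, length.out = 9),
                  seq(-0.02, 0.02, length.out = 9))
}

full_window <- search_window(lo = c(-0.001, -0.021, -0.021),
                             hi = c(0.101, 0.021, 0.021))

test_that("locate_core finds the grid point nearest a single Gaussian well", {
  g <- tracking_grid()
  x0 <- c(0.043, 0.002, -0.003)
  ser <- moving_min_series(function(t) x0, g, depth = 10, width = 4e-3,
                           n_steps = 2)
  res <- locate_core(ser$snapshots[[1]], full_window, local_frame)
  d2 <- rowSums(sweep(g$points, 2, x0)^2)
  expect_equal(res$index, which.min(d2))
})

test_that("the deeper of two wells wins", {
  g <- tracking_grid()
  pts <- g$points
  x1 <- c(0.07, 0, 0); x2 <- c(0.02, 0, 0)
  p <- -5 * exp(-rowSums(sweep(pts, 2, x2)^2) / (2 * 16e-6)) -
       10 * exp(-rowSums(sweep(pts, 2, x1)^2) / (2 * 16e-6))
  s <- flow_snapshot(g, matrix(0, nrow(pts), 3), p)
  res <- locate_core(s, full_window, local_frame)
  expect_lt(sqrt(sum((res$point - x1)^2)), 0.006)
})

test_that("locate_core equals the exhaustive argmin at every phase", {
  g <- tracking_grid()
  ser <- moving_min_series(function(t) c(0.02 + 0.06 * t, 0.004 * sin(2 * pi * t), 0),
                           g, depth = 20, width = 5e-3, n_steps = 25)
  for (s in ser$snapshots) {
    res <- locate_core(s, full_window, local_frame)
    expect_identical(res$index, which.min(s$pressure))
  }
})

test_that("empty windows and flat pressure are handled explicitly", {
  g <- tracking_grid()
  s <- flow_snapshot(g, matrix(0, nrow(g$points), 3), rep(1, nrow(g$points)))
  far <- search_window(lo = c(10, 10, 10), hi = c(11, 11, 11))
  expect_error(locate_core(s, far, local_frame), "no candidate")
  expect_warning(res <- locate_core(s, full_window, local_frame), "equal")
  expect_equal(res$xi[1], min(to_sinus_frame(local_frame, g$points)[, 1]))
})

test_that("a stationary well tracks to a constant axial coordinate", {
  g <- tracking_grid()
  ser <- moving_min_series(function(t) c(0.05, 0, 0), g, depth = 10,
                           width = 4e-3, n_steps = 12)
  traj <- track_core(ser, full_window, local_frame)
  cell <- diff(g$x)[1]
  expect_lt(diff(range(traj$xi)), cell)
})

test_that("a constant-speed well is recovered with the right slope", {
  g <- tracking_grid(41)
  v0 <- 0.05
  ser <- moving_min_series(function(t) c(0.02 + v0 * t, 0, 0), g, depth = 10,
                           width = 4e-3, n_steps = 40)
  traj <- track_core(ser, full_window, local_frame)
  slope <- stats::coef(stats::lm(xi ~ t, data = as.data.frame(traj)))[2]
  expect_equal(unname(slope), v0, tolerance = 0.05)
})

test_that("a decelerate-stall-reverse trajectory is recovered to one cell", {
  g <- tracking_grid(101)
  # advances, stalls at t* = 0.5, then retreats (quadratic in t)
  xi_true <- function(t) 0.03 + 0.08 * t - 0.08 * t^2
  ser <- moving_min_series(function(t) c(xi_true(t), 0, 0), g, depth = 10,
                           width = 4e-3, n_steps = 40)
  traj <- track_core(ser, full_window, local_frame)
  cell <- diff(g$x)[1]
  expect_lt(max(abs(traj$xi - xi_true(traj$t))), cell)
  kin <- trajectory_kinematics(traj, smooth_window = 3)
  still <- kin$events[kin$events$type == "stillstand", ]
  expect_gte(nrow(still), 1L)
  expect_lt(min(abs(still$phase - 0.5)), ser$dt / ser$T_period + 1e-9)
  # the stall is also an upstream-motion onset
  expect_true("upstream_onset" %in% kin$events$type)
})

test_that("kinematics of linear and quadratic trajectories are exact", {
  n <- 21
  t <- seq(0, 1, length.out = n)
  mk_traj <- function(xi) {
    structure(data.frame(t = t, phase = t, x = xi, y = 0, z = 0, xi = xi,
                         eta = 0, zeta = 0, p = 0, p_over_P0 = NA_real_),
              truncated_at = NA_real_,
              class = c("core_trajectory", "data.frame"))
  }
  lin <- trajectory_kinematics(mk_traj(0.01 + 0.03 * t), smooth_window = 1)
  expect_equal(lin$velocity, rep(0.03, n), tolerance = 1e-10)
  expect_lt(max(abs(lin$acceleration)), 1e-8)
  expect_equal(nrow(lin$events), 0L)
  quad <- trajectory_kinematics(mk_traj(0.01 + 0.05 * t^2), smooth_window = 1)
  inner <- 2:(n - 1)
  expect_equal(quad$acceleration[inner], rep(0.1, n - 2), tolerance = 1e-6)
})

test_that("five seeded random trajectories stay within one cell / velocity bound", {
  g <- tracking_grid(41)
  cell <- diff(g$x)[1]
  n_steps <- 40
  for (seed in 1:5) {
    set.seed(seed)
    a <- runif(2, -0.01, 0.01); b <- runif(1, 0.02, 0.05)
    xi_true <- function(t) 0.045 + b * (t - 0.5) + a[1] * sin(2 * pi * t) +
      a[2] * cos(4 * pi * t)
    ser <- moving_min_series(function(t) c(xi_true(t), 0, 0), g, depth = 10,
                             width = 4e-3, n_steps = n_steps)
    traj <- track_core(ser, full_window, local_frame)
    expect_lt(max(abs(traj$xi - xi_true(traj$t))), cell)
    kin <- trajectory_kinematics(traj, smooth_window = 1)
    h <- 1e-5
    v_true <- (xi_true(traj$t + h) - xi_true(traj$t - h)) / (2 * h)
    expect_lt(max(abs(kin$velocity - v_true)), 2 * cell / ser$dt)
  }
})

test_that("tracking is deterministic: identical inputs, identical trajectories", {
  g <- tracking_grid()
  ser <- moving_min_series(function(t) c(0.02 + 0.05 * t, 0, 0), g, depth = 10,
                           width = 4e-3, n_steps = 15)
  t1 <- track_core(ser, full_window, local_frame)
  t2 <- track_core(ser, full_window, local_frame)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
})

test_that("an advected window follows its prescribed speed", {
  g <- tracking_grid(41)
  v0 <- 0.05
  ser <- moving_min_series(function(t) c(0.02 + v0 * t, 0, 0), g, depth = 10,
                           width = 3e-3, n_steps = 40)
  # narrow window that only holds the well if advected correctly
  win <- search_window(lo = c(0.005, -0.021, -0.021),
                       hi = c(0.035, 0.021, 0.021), mode = "advected",
                       advection_velocity = v0)
  traj <- track_core(ser, win, local_frame)
  expect_equal(nrow(traj), 40L)
  expect_lt(max(abs(traj$xi - (0.02 + v0 * traj$t))), diff(g$x)[1])
})

test_that("core pressure is nondimensionalized by the reference-phase P0", {
  g <- tracking_grid()
  ser <- moving_min_series(function(t) c(0.05, 0, 0), g, depth = 10,
                           width = 4e-3, p_background = 100, n_steps = 10)
  traj <- track_core(ser, full_window, local_frame, p0_phase = 0.191,
                     p0_point = c(0, 0, 0))
  expect_false(any(is.na(traj$p_over_P0)))
  expect_equal(traj$p_over_P0, traj$p / attr(traj, "P0"))
})
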