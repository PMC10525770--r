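unit_fluid <- fluid_properties(nu = 1, rho = 1)   # mu = 1

wss_on_pipe <- function(a, U, y, fluid = unit_fluid, order = 1L) {
  wall <- pipe_wall_patch(a, L = a, n_theta = 16, n_x = 4, y = y)
  snap <- poiseuille_snapshot(a, U, fluid, rbind(wall$samples, wall$samples2),
                              clip = FALSE)
  compute_wss(snap, wall, fluid, order = order)
}

test_that("Poiseuille WSS magnitude matches 4 mu U / a on every face", {
  w <- wss_on_pipe(a = 1, U = 0.5, y = 1 / 100)
  expect_lt(max(abs(w$mag - 2.0)) / 2.0, 0.01)
  # the WSS vector is tangent to the wall
  wall <- pipe_wall_patch(1, L = 1, n_theta = 16, n_x = 4, y = 1 / 100)
  expect_lt(max(abs(rowSums(w$tau * wall$normals))), 1e-8 * max(w$mag))
})

test_that("zero flow gives identically zero WSS", {
  w <- wss_on_pipe(a = 1, U = 0, y = 0.01)
  expect_true(all(w$tau == 0))
})

test_that("WSS scales linearly with viscosity", {
  w1 <- wss_on_pipe(1, 0.5, 0.01, fluid_properties(nu = 1, rho = 1))
  w2 <- wss_on_pipe(1, 0.5, 0.01, fluid_properties(nu = 1, rho = 2))
  expect_identical(2 * w1$tau, w2$tau)
})

test_that("first-order wall derivative error halves with the sample distance", {
  e <- function(y) max(abs(wss_on_pipe(1, 0.5, y)$mag - 2.0))
  expect_equal(e(0.02) / e(0.01), 2, tolerance = 0.05)
})

test_that("Womersley per-phase wall shear is recovered within 2% of the analytic trace", {
  a <- 3.25e-3; fl <- fluid_properties(); wf <- make_waveform(fluid = fl)
  y <- a / 64
  wall <- pipe_wall_patch(a, L = 2e-3, n_theta = 8, n_x = 2, y = y)
  ser <- womersley_series(a, wf, fl, rbind(wall$samples, wall$samples2),
                          n_steps = 200, clip = FALSE)
  gt <- ground_truth(ser)
  scale <- max(abs(gt$tau_wall_series))
  err <- vapply(seq_along(ser$snapshots), function(i) {
    w <- compute_wss(ser$snapshots[[i]], wall, fl, order = 2L)
    max(abs(w$mag - abs(gt$tau_wall_series[i])))
  }, 0)
  expect_lt(max(err) / scale, 0.02)
})

test_that("TAWSS equals the constant it averages, and 2A/pi for A|sin|", {
  mk <- function(mag, t) {
    structure(list(tau = matrix(mag / sqrt(3), 1, 3), mag = mag, t = t,
                   phase = t, order = 1L, fluid = unit_fluid),
              class = "wss_field")
  }
  tt <- (0:199) / 200
  const <- compute_tawss(lapply(tt, function(t) mk(3.7, t)), 1)
  expect_identical(const$tawss, 3.7)
  A <- 2
  tw <- compute_tawss(lapply(tt, function(t) mk(A * abs(sin(2 * pi * t)), t)), 1)
  expect_equal(tw$tawss, 2 * A / pi, tolerance = 1e-3)
  # a single-phase "cycle" is that phase itself
  expect_identical(compute_tawss(list(mk(1.3, 0)), 1)$tawss, 1.3)
  # non-uniform phases are rejected
  expect_error(compute_tawss(list(mk(1, 0), mk(1, 0.3), mk(1, 0.4)), 1),
               "uniform")
})

test_that("TAWSS agrees with a dense Simpson quadrature on random traces", {
  set.seed(42)
  coefs <- replicate(5, list(a = runif(3, -1, 1), b = runif(3, -1, 1),
                             c0 = runif(1, 2, 4)), simplify = FALSE)
  trace_fun <- function(cf) function(t) {
    v <- cf$c0
    for (k in 1:3) v <- v + cf$a[k] * sin(2 * pi * k * t) +
        cf$b[k] * cos(2 * pi * k * t)
    abs(v)
  }
  simpson <- function(f, n = 10000) {
    x <- seq(0, 1, length.out = n + 1)
    w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    sum(w * f(x)) / (3 * n)
  }
  for (cf in coefs) {
    f <- trace_fun(cf)
    tt <- (0:99) / 100
    mk <- function(t) structure(list(tau = matrix(0, 1, 3), mag = f(t), t = t,
                                     phase = t, order = 1L),
                                class = "wss_field")
    tw <- compute_tawss(lapply(tt, mk), 1)
    expect_equal(tw$tawss, simpson(f), tolerance = 5e-3)
  }
})

test_that("overlap coefficient: empty, identity, and near-wall vortex cases", {
  a <- 1
  wall <- pipe_wall_patch(a, L = 2, n_theta = 24, n_x = 6, y = 0.02)
  snap <- poiseuille_snapshot(a, 0.5, unit_fluid,
                              rbind(wall$samples, wall$samples2), clip = FALSE)
  w <- compute_wss(snap, wall, unit_fluid)
  expect_warning(ov0 <- wss_vortex_overlap(w, list(), wall, d = 0.1),
                 "no vortex regions")
  expect_identical(as.numeric(ov0), 0)

  # identity: a fake region placed exactly at the top-q faces
  wmod <- w
  hot <- 1:36                                 # top faces by construction
  wmod$mag <- rep(1, length(w$mag)); wmod$mag[hot] <- 2
  fake <- structure(list(points = wall$centers[hot, , drop = FALSE], n = 36L),
                    class = "vortex_region")
  ov1 <- wss_vortex_overlap(wmod, list(fake), wall, q = 1 - 36 / length(w$mag),
                            d = 1e-6)
  expect_equal(as.numeric(ov1), 1.0)
})

test_that("a vortex hugging the wall overlaps the high-WSS band beyond chance", {
  a <- 1; r_c <- 0.15
  g <- structured_grid(seq(-1.1, 1.1, length.out = 23))
  tube <- vortex_tube_field("lamb_oseen", g, Gamma = 2, r_c = r_c,
                            axis_point = c(0, a - 1.5 * r_c, 0),
                            axis_dir = c(1, 0, 0))
  pois <- poiseuille_snapshot(a, 0.5, unit_fluid, g, clip = FALSE)
  snap <- flow_snapshot(g, tube$velocity + pois$velocity, tube$pressure)
  l2 <- lambda2_field(velocity_gradient(snap))
  regs <- extract_vortex_regions(l2, -0.05 * quantile(abs(l2$lambda2), 0.99,
                                                      names = FALSE),
                                 min_size = 5)
  wall <- pipe_wall_patch(a, x0 = -1, L = 2, n_theta = 20, n_x = 8, y = 0.04)
  w <- compute_wss(snap, wall, unit_fluid)
  ov <- as.numeric(wss_vortex_overlap(w, regs, wall, q = 0.8, d = 0.25))
  # permutation null: random same-size footprints
  set.seed(99)
  nf <- length(attr(wss_vortex_overlap(w, regs, wall, q = 0.8, d = 0.25),
                    "footprint_faces"))
  high <- which(w$mag > quantile(w$mag, 0.8))
  null <- replicate(500, {
    foot <- sample(nrow(wall$centers), nf)
    length(intersect(high, foot)) / min(length(high), nf)
  })
  expect_gt(ov, mean(null))
})
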