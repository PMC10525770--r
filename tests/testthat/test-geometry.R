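# geometry builds are cached per file run: building is the expensive step
healthy <- build_geometry(cab_preset("healthy"))
predisposed <- build_geometry(cab_preset("predisposed"))

test_that("packaged presets measure back to their anatomical targets", {
  mh <- measure_geometry(healthy)
  expect_equal(mh$ica_branch_angle, 30, tolerance = 0.5 / 30)
  expect_equal(mh$eca_branch_angle, 30, tolerance = 0.5 / 30)
  expect_equal(mh$total_branch_angle, 60, tolerance = 0.5 / 60)
  expect_equal(mh$ica_cca_diameter_ratio, 0.7, tolerance = 0.01 / 0.7)
  expect_equal(mh$cca_inlet_diameter, 6.5e-3, tolerance = 0.01)
  mp <- measure_geometry(predisposed)
  expect_equal(mp$ica_branch_angle, 45, tolerance = 0.5 / 45)
  expect_equal(mp$total_branch_angle, 75, tolerance = 0.5 / 75)
  expect_equal(mp$ica_cca_diameter_ratio, 0.5, tolerance = 0.01 / 0.5)
})

test_that("constructed surfaces are watertight with outward normals", {
  for (geom in list(healthy, predisposed)) {
    wt <- mesh_is_watertight(geom$surface)
    expect_true(wt$watertight)
    expect_identical(wt$n_boundary_edges, 0L)
    expect_identical(wt$n_nonmanifold_edges, 0L)
    # outward normals: stepping along the normal leaves the lumen
    v <- geom$surface$vertices[geom$surface$faces[, 1], ]
    probe <- v + 1e-5 * geom$surface$normals
    expect_gt(mean(geom$sdf(probe) > 0), 0.99)
  }
})

test_that("every face carries a branch label and the sinus is on the ICA", {
  lab <- healthy$surface$labels
  expect_true(all(lab %in% c("cca", "ica", "eca", "sinus")))
  expect_gt(sum(lab == "sinus"), 0)
  cent <- (healthy$surface$vertices[healthy$surface$faces[, 1], ] +
             healthy$surface$vertices[healthy$surface$faces[, 2], ] +
             healthy$surface$vertices[healthy$surface$faces[, 3], ]) / 3
  expect_true(all(cent[lab == "sinus", 2] > 0))   # ICA side is +y
})

test_that("a sinus bulge equal to the downstream diameter degenerates to a tube", {
  p <- cab_parameters(ica_cca_diameter_ratio = 0.7,
                      sinus_max_diameter = 0.7 * 6.5e-3)
  g <- build_geometry(p)
  m <- measure_geometry(g)
  expect_equal(m$sinus_max_diameter, 0.7 * 6.5e-3, tolerance = 0.005)
  expect_equal(m$ica_cca_diameter_ratio, 0.7, tolerance = 0.01 / 0.7)
})

test_that("measure after build round-trips random valid parameter sets", {
  set.seed(2024)
  for (k in 1:20) {
    D <- runif(1, 5e-3, 8e-3)
    p <- cab_parameters(
      cca_inlet_diameter = D,
      ica_cca_diameter_ratio = runif(1, 0.45, 0.85),
      ica_branch_angle = runif(1, 25, 50),
      eca_branch_angle = runif(1, 20, 40),
      sinus_max_diameter = runif(1, 1.05, 1.2) * D,
      cca_taper_ratio = runif(1, 0.85, 0.95))
    m <- measure_geometry(build_geometry(p))
    expect_lt(abs(m$ica_branch_angle - p$ica_branch_angle), 0.5)
    expect_lt(abs(m$eca_branch_angle - p$eca_branch_angle), 0.5)
    expect_lt(abs(m$cca_inlet_diameter - p$cca_inlet_diameter) /
                p$cca_inlet_diameter, 0.01)
    expect_lt(abs(m$ica_cca_diameter_ratio - p$ica_cca_diameter_ratio) /
                p$ica_cca_diameter_ratio, 0.01)
    expect_lt(abs(m$sinus_max_diameter - p$sinus_max_diameter) /
                p$sinus_max_diameter, 0.01)
  }
})

test_that("cross-section area varies continuously along the ICA", {
  seg <- healthy$sinus_segment
  ss <- seq(seg[1] + 0.3 * diff(seg), healthy$branch_lengths$ica * 0.9,
            by = healthy$h)   # adjacent stations at the mesh resolution
  dd <- vapply(ss, function(s) cabvort:::.section_diameter(healthy, "ica", s), 0)
  expect_lt(max(abs(diff(dd^2)) / dd[-1]^2), 0.20)
})

test_that("measured dimensions are insensitive to the mesh resolution", {
  p <- cab_preset("healthy")
  g1 <- build_geometry(p, h = 1.2e-3)
  g2 <- build_geometry(p, h = 0.6e-3)
  m1 <- measure_geometry(g1); m2 <- measure_geometry(g2)
  expect_lt(abs(m1$ica_branch_angle - m2$ica_branch_angle), 0.2)
  expect_lt(abs(m1$cca_inlet_diameter - m2$cca_inlet_diameter) /
              m2$cca_inlet_diameter, 0.002)
  expect_lt(abs(m1$sinus_max_diameter - m2$sinus_max_diameter) /
              m2$sinus_max_diameter, 0.002)
})

test_that("invalid parameters are rejected naming the offending field", {
  expect_error(cab_parameters(cca_inlet_diameter = -1), "cca_inlet_diameter")
  expect_error(cab_parameters(ica_cca_diameter_ratio = 1.4),
               "ica_cca_diameter_ratio")
  expect_error(cab_parameters(ica_branch_angle = 95), "ica_branch_angle")
  expect_error(cab_parameters(sinus_max_diameter = 1e-4), "sinus_max_diameter")
  g2 <- healthy
  g2$surface$labels <- NULL
  expect_error(measure_geometry(g2), "unlabeled")
})

test_that("the sinus frame is orthonormal and anchored at the apex", {
  fr <- sinus_frame(healthy)
  B <- cbind(fr$axial, fr$e2, fr$e3)
  expect_lt(max(abs(crossprod(B) - diag(3))), 1e-12)
  expect_equal(drop(to_sinus_frame(fr, healthy$apex)), c(0, 0, 0))
  # a point at arc distance d down the ICA axis has xi = d
  d <- 0.011
  pt <- healthy$apex + d * healthy$branch_dirs$ica
  expect_equal(to_sinus_frame(fr, pt)[1, 1], d, tolerance = 1e-12)
  # round trip
  xi <- to_sinus_frame(fr, matrix(rnorm(9, 0, 5e-3), 3))
  expect_equal(from_sinus_frame(fr, xi),
               from_sinus_frame(fr, to_sinus_frame(fr, from_sinus_frame(fr, xi))),
               tolerance = 1e-12)
  expect_error(sinus_frame(list(apex = c(0, 0, 0),
                                branch_dirs = list(ica = c(0, 0, 0)))),
               "degenerate")
})

test_that("surface and centerline exports are written and consistent", {
  stl <- withr::local_tempfile(fileext = ".stl")
  write_stl(healthy$surface, stl)
  lines <- readLines(stl)
  expect_identical(sum(grepl("^facet normal", lines)),
                   nrow(healthy$surface$faces))
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_polydata(healthy$surface, vtk,
                     cell_data = list(sinus = as.numeric(healthy$surface$labels == "sinus")))
  expect_true(any(grepl("^POLYGONS", readLines(vtk))))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_centerlines_csv(healthy, csv)
  cl <- utils::read.csv(csv)
  expect_setequal(unique(cl$branch), c("cca", "ica", "eca"))
  expect_true(all(diff(cl$arclength[cl$branch == "ica"]) > 0))
})
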