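test_that("polygon area matches closed forms and a Monte-Carlo oracle", {
  expect_equal(cell_area(rect_polygon(1, 1)), 1.0)
  # regular 360-gon of circumradius 1 approaches pi
  expect_equal(cell_area(regular_polygon(360)), pi, tolerance = 1e-3)
  # random 12-gon vs rejection-sampling oracle
  set.seed(11)
  th <- sort(runif(12, 0, 2 * pi))
  r <- runif(12, 0.5, 1.5)
  poly <- cbind(r * cos(th), r * sin(th))
  a <- cell_area(poly)
  set.seed(12)
  n <- 2e5
  px <- runif(n, min(poly[, 1]), max(poly[, 1]))
  py <- runif(n, min(poly[, 2]), max(poly[, 2]))
  box <- diff(range(poly[, 1])) * diff(range(poly[, 2]))
  a_mc <- box * mean(cardiomorph:::points_in_poly(px, py, poly))
  expect_equal(a, a_mc, tolerance = 0.01)
})

test_that("circularity reproduces regular-polygon closed forms", {
  expect_equal(cell_circularity(rect_polygon(1, 1)), pi / 4, tolerance = 1e-12)
  expect_gte(cell_circularity(regular_polygon(720)), 0.999)
  for (k in c(3, 5, 6)) {
    expect_equal(cell_circularity(regular_polygon(k)),
                 pi / (k * tan(pi / k)), tolerance = 1e-12)
  }
})

test_that("orientation and elongation come from exact polygon moments", {
  o <- cell_orientation(rect_polygon(2, 1))
  expect_equal(o$orientation_axis_deg, 0)
  expect_equal(o$elongation, 0.75, tolerance = 1e-12)
  o30 <- cell_orientation(rotate_poly(rect_polygon(2, 1), 30))
  expect_equal(o30$orientation_axis_deg, 30, tolerance = 1e-6)
  expect_equal(o30$elongation, 0.75, tolerance = 1e-12)
  # isotropic shape: undefined axis
  osq <- cell_orientation(regular_polygon(4))
  expect_true(is.na(osq$orientation_axis_deg))
  expect_equal(osq$elongation, 0)
})

test_that("orientation matches a dense rasterisation oracle", {
  set.seed(5)
  th <- sort(runif(9, 0, 2 * pi))
  r <- runif(9, 2, 5)
  poly <- cbind(r * cos(th), r * sin(th))
  o <- cell_orientation(poly)
  # oracle: pixel covariance at 0.05 um/px
  h <- 0.05
  gx <- seq(min(poly[, 1]), max(poly[, 1]), by = h)
  gy <- seq(min(poly[, 2]), max(poly[, 2]), by = h)
  gg <- expand.grid(x = gx, y = gy)
  ins <- cardiomorph:::points_in_poly(gg$x, gg$y, poly)
  cv <- stats::cov(gg[ins, ])
  ev <- eigen(cv, symmetric = TRUE)
  ax <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  expect_lt(abs(fold_axial(o$orientation_axis_deg - ax)), 0.5)
})

test_that("shape measures are rigid-motion invariant and scale correctly", {
  set.seed(3)
  th <- sort(runif(10, 0, 2 * pi))
  poly <- cbind(3 * runif(10, 0.6, 1) * cos(th), runif(10, 0.6, 1) * sin(th))
  for (ang in c(17, 121, 290)) {
    mv <- rotate_poly(poly, ang) + matrix(c(7, -3), 10, 2, byrow = TRUE)
    expect_equal(cell_area(mv), cell_area(poly), tolerance = 1e-9)
    expect_equal(cell_perimeter(mv), cell_perimeter(poly), tolerance = 1e-9)
    expect_equal(cell_circularity(mv), cell_circularity(poly),
                 tolerance = 1e-9)
    o0 <- cell_orientation(poly); o1 <- cell_orientation(mv)
    expect_equal(o1$elongation, o0$elongation, tolerance = 1e-9)
    expect_lt(abs(fold_axial(o1$orientation_axis_deg -
                               o0$orientation_axis_deg - ang)), 1e-6)
  }
  s <- 2.5
  expect_equal(cell_area(poly * s), s^2 * cell_area(poly), tolerance = 1e-9)
  expect_equal(cell_perimeter(poly * s), s * cell_perimeter(poly),
               tolerance = 1e-9)
  expect_equal(cell_circularity(poly * s), cell_circularity(poly),
               tolerance = 1e-9)
})

test_that("circularity never exceeds 1 on convex fixtures", {
  for (k in c(3, 4, 5, 6, 12, 60, 720)) {
    expect_lte(cell_circularity(regular_polygon(k)), 1.0001)
  }
})

test_that("region summaries report means, sd and Welch comparison", {
  cells <- list(
    list(id = 1, boundary = rect_polygon(2, 2), region = "A"),
    list(id = 2, boundary = rect_polygon(2.2, 2) + 5, region = "A"),
    list(id = 3, boundary = rect_polygon(3, 3) + 10, region = "B"),
    list(id = 4, boundary = rect_polygon(3.4, 3) + 15, region = "B"))
  mesh <- mesh_from_polygons(cells, snap_tol_um = 1e-9)
  for (i in seq_along(mesh$cells)) mesh$cells[[i]]$region <-
      c("A", "A", "B", "B")[i]
  sh <- measure_cells(mesh, smooth = FALSE)
  sm <- summarise_regions(sh, compare = c("A", "B"))
  expect_equal(sm$table$area_mean, c(mean(c(4, 4.4)), mean(c(9, 10.2))))
  expect_s3_class(sm$welch$area, "htest")
  expect_lt(sm$welch$area$p.value, 0.2)
  # identical cells in one region: zero dispersion
  sh_same <- rbind(sh[1, ], sh[1, ]); sh_same$cell_id <- 1:2
  expect_equal(summarise_regions(sh_same)$table$area_sd, 0)
  # single-cell region: sd reported NA by default
  sh1 <- sh[c(1, 3), ]; sh1$region <- c("A", "B")
  expect_true(is.na(summarise_regions(sh1)$table$area_sd[1]))
  expect_equal(summarise_regions(sh1, sd_single = 0)$table$area_sd[1], 0)
})

test_that("window-3 smoothing preserves area within 2 percent on raster cells", {
  tis <- cached_tissue(1)
  for (cl in tis$mesh$cells[seq(1, length(tis$mesh$cells), by = 7)]) {
    a_raw <- cell_area(cl$boundary)
    a_sm <- cell_area(smooth_polygon(cl$boundary))
    expect_lt(abs(a_sm - a_raw) / a_raw, 0.02)
  }
})
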