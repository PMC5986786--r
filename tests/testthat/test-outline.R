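test_that("smoothing a circle trace reproduces the circle and its centre", {
  tr <- circle_trace(24, r = 50, centre = c(60, 60))
  sm <- smooth_outline(tr)
  rr <- sqrt(rowSums(sweep(sm$samples, 2, c(60, 60))^2))
  expect_true(all(abs(rr - 50) / 50 < 0.005))
  expect_lt(sqrt(sum((sm$centroid - c(60, 60))^2)), 0.5)
})

test_that("smoothed square arc length lies between inscribed circle and square", {
  s <- 40
  tr <- rbind(c(0, 0), c(s / 2, 0), c(s, 0), c(s, s / 2), c(s, s),
              c(s / 2, s), c(0, s), c(0, s / 2))
  sm <- smooth_outline(tr)
  expect_gt(sm$total_arc, pi * s)      # inscribed circle perimeter
  # the interpolating spline overshoots slightly at the corners, so allow
  # a small margin above the square perimeter
  expect_lt(sm$total_arc, 4 * s * 1.03)
  # oracle: the same constructed curve at 10x sampling density
  sm10 <- smooth_outline(tr, samples_per_span = 200)
  expect_equal(sm$total_arc, sm10$total_arc, tolerance = 1e-3)
})

test_that("duplicate trace points are dropped with a warning, curve unchanged", {
  tr <- circle_trace(24)
  tr_dup <- rbind(tr[1:10, ], tr[10, ], tr[11:24, ])
  expect_warning(sm2 <- smooth_outline(traced_outline(tr_dup)), "duplicate")
  sm1 <- smooth_outline(tr)
  expect_equal(sm1$samples, sm2$samples)
})

test_that("landmarks 5 and 6 trisect the outer-curvature arc", {
  # circle with lm3 at 0 deg and lm4 at 180 deg: thirds at 60 and 120 deg
  ctr <- c(60, 60)
  tr <- circle_trace(36, r = 50, centre = ctr)
  deg_pt <- function(d) ctr + 50 * c(cos(d * pi / 180), sin(d * pi / 180))
  lm <- rbind(deg_pt(270), deg_pt(315), deg_pt(0), deg_pt(180))
  ls <- place_landmarks(smooth_outline(tr), lm)
  a5 <- atan2(ls$points[5, 2] - ctr[2], ls$points[5, 1] - ctr[1]) * 180 / pi
  a6 <- atan2(ls$points[6, 2] - ctr[2], ls$points[6, 1] - ctr[1]) * 180 / pi
  expect_equal(a5, 60, tolerance = 0.5)
  expect_equal(a6, 120, tolerance = 0.5)
})

test_that("arc trisection is exact against a dense arc-length table", {
  # 2:1 ellipse
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  tr <- cbind(80 + 60 * cos(th), 50 + 30 * sin(th))
  sm <- smooth_outline(tr, samples_per_span = 40)
  pt <- function(d) c(80 + 60 * cos(d), 50 + 30 * sin(d))
  lm <- rbind(pt(pi), pt(3 * pi / 2), pt(0), pt(pi / 2))
  ls <- place_landmarks(sm, lm)
  L <- sm$total_arc
  seg1 <- (ls$arc[5] - ls$arc[3]) %% L
  seg2 <- (ls$arc[6] - ls$arc[5]) %% L
  seg3 <- (ls$arc[4] - ls$arc[6]) %% L
  expect_lt(abs(seg1 - seg2) / seg1, 1e-6)
  expect_lt(abs(seg2 - seg3) / seg2, 1e-6)
  # and the computed points really lie at those arc positions on the curve
  p5 <- cardiomorph:::outline_point_at_arc(sm, ls$arc[5])
  expect_close(p5, ls$points[5, ], 1e-9)
})

test_that("snapping a landmark already on a sample is the identity", {
  tr <- circle_trace(24, r = 50, centre = c(60, 60))
  sm <- smooth_outline(tr)
  lm_pts <- sm$samples[c(300, 360, 1, 140), ]  # on-curve, CCW order 1,2,3,4
  ls <- place_landmarks(sm, lm_pts)
  expect_equal(unname(ls$points[1:4, ]), unname(lm_pts))
})

test_that("landmark validation errors are specific", {
  sm <- smooth_outline(circle_trace(24, r = 50, centre = c(60, 60)))
  lm_far <- rbind(c(60, 60), c(110, 60), c(60, 110), c(10, 60))
  expect_error(place_landmarks(sm, lm_far), "lm1")
  deg_pt <- function(d) c(60, 60) + 50 * c(cos(d * pi / 180),
                                           sin(d * pi / 180))
  lm_bad <- rbind(deg_pt(0), deg_pt(270), deg_pt(90), deg_pt(180))
  expect_error(place_landmarks(sm, lm_bad), "order")
})

test_that("sector widths on a circle match analytic polar intervals", {
  ctr <- c(60, 60)
  sm <- smooth_outline(circle_trace(36, r = 50, centre = ctr))
  deg_pt <- function(d) ctr + 50 * c(cos(d * pi / 180), sin(d * pi / 180))
  lm <- rbind(deg_pt(0), deg_pt(40), deg_pt(90), deg_pt(270))
  ls <- place_landmarks(sm, lm)
  pa <- partition_segments(sm, ls)
  segs <- pa$segments
  expect_equal(segs$name, c("IC", "OFT", "OC_near_OFT", "OC_middle",
                            "OC_near_AV", "AV"))
  expect_equal(segs$width_deg[segs$name == "IC"], 40, tolerance = 0.5)
  expect_equal(segs$width_deg[segs$name == "OFT"], 50, tolerance = 0.5)
  expect_equal(sum(segs$width_deg), 360, tolerance = 1e-9)
  # OC sub-sectors trisect the 90 -> 270 arc: 60 degrees each
  expect_equal(segs$width_deg[grepl("OC", segs$name)], rep(60, 3),
               tolerance = 0.5)
})

test_that("sectors partition the plane: every sample in exactly one sector", {
  tis <- cached_tissue(1)
  pa <- tis$partition
  sm <- tis$smoothed
  reg <- segment_of_points(pa, sm$samples)
  expect_false(any(is.na(reg)))
  # brute-force oracle: angular membership per sector, counted per point
  ctr <- pa$centroid
  ang <- atan2(sm$samples[, 2] - ctr[2], sm$samples[, 1] - ctr[1]) * 180 / pi
  ang <- ang %% 360
  counts <- rep(0, length(ang))
  on_boundary <- rep(FALSE, length(ang))
  for (k in seq_len(6)) {
    rel <- (ang - pa$segments$from_deg[k]) %% 360
    counts <- counts + (rel < pa$segments$width_deg[k])
    on_boundary <- on_boundary | rel < 1e-9 |
      abs(rel - pa$segments$width_deg[k]) < 1e-9
  }
  # exactly one sector everywhere; representation ties only on boundary rays
  expect_true(all(counts == 1 | on_boundary))
  expect_true(all(counts >= 1))
})

test_that("cell centroids get exactly one region and match the ground truth", {
  for (seed in 1:2) {
    tis <- cached_tissue(seed)
    mesh <- assign_cell_regions(tis$mesh, tis$partition)
    regs <- vapply(mesh$cells, function(cl) cl$region, character(1))
    expect_false(any(is.na(regs)))
    expect_equal(regs, tis$truth$cells$region)
  }
})

test_that("axial angle conventions behave as defined", {
  ctr <- c(60, 60)
  sm <- smooth_outline(circle_trace(36, r = 50, centre = ctr))
  # cell at angle 0 deg on the circle: outward normal along +x (0 deg),
  # tangent along +y (90 deg)
  cell_pos <- ctr + c(45, 0)
  expect_equal(axial_angle(0, sm, cell_pos, "normal"), 0, tolerance = 0.5)
  expect_equal(axial_angle(90, sm, cell_pos, "normal"), 90, tolerance = 0.5)
  expect_equal(axial_angle(90, sm, cell_pos, "tangent"), 0, tolerance = 0.5)
  # axial identity: psi and psi + 180 are the same axis
  expect_equal(axial_angle(23, sm, cell_pos), axial_angle(23 + 180, sm, cell_pos))
})

test_that("axial angles match a brute-force representative oracle", {
  ctr <- c(60, 60)
  sm <- smooth_outline(circle_trace(36, r = 50, centre = ctr))
  set.seed(8)
  for (i in 1:20) {
    th <- runif(1, 0, 2 * pi)
    pos <- ctr + 45 * c(cos(th), sin(th))
    psi <- runif(1, 0, 180)
    got <- axial_angle(psi, sm, pos, "normal")
    # oracle: minimise |angle| over the four axis/normal sign representations
    nrm <- th * 180 / pi   # exact outward normal of the circle
    cands <- c(psi - nrm, psi - nrm + 180, psi - nrm - 180, psi - nrm + 360)
    cands <- ((cands + 90) %% 180) - 90
    cands[cands == -90] <- 90
    best <- cands[which.min(abs(cands))]
    expect_equal(got, best, tolerance = 1)  # tangent discretisation ~0.5 deg
  }
})

test_that("angles, regions and looping are rigid-motion equivariant", {
  tis <- cached_tissue(1)
  mesh <- tis$mesh
  sh <- measure_cells(mesh)
  ang0 <- cell_axial_angles(mesh, tis$smoothed, sh)
  phi <- 33
  rot <- function(p) rotate_poly(p, phi, centre = c(0, 0))
  # rotate outline trace and all cell polygons
  tr_rot <- traced_outline(rot(tis$outline$points))
  sm_rot <- smooth_outline(tr_rot)
  polys <- lapply(mesh$cells, function(cl)
    list(id = cl$id, boundary = rot(cl$boundary)))
  mesh_rot <- mesh_from_polygons(polys, snap_tol_um = 1e-9)
  sh_rot <- measure_cells(mesh_rot)
  ang_rot <- cell_axial_angles(mesh_rot, sm_rot, sh_rot)
  ok <- !is.na(ang0$angle_deg) & !is.na(ang_rot$angle_deg)
  d <- abs(fold_axial(ang_rot$angle_deg[ok] - ang0$angle_deg[ok]))
  # folding at the +/-90 boundary can flip representatives; compare axially
  expect_lt(stats::median(d), 0.2)
  expect_lt(mean(d > 1), 0.05)
})

test_that("looping angle handles canonical and degenerate inputs", {
  expect_equal(looping_angle(c(0, 0), c(0, 2), c(0, 1)), 0)
  expect_equal(looping_angle(c(0, 0), c(2, 0), c(0, 1)), 90)
  expect_equal(looping_angle(c(0, 0), c(1, 1), c(0, 1)), 45)
  # endpoint swap and midline sign invariance
  expect_equal(looping_angle(c(1, 1), c(0, 0), c(0, -1)), 45)
  a <- looping_angle(c(2, 1), c(5, -2), c(1, 3))
  expect_equal(looping_angle(c(5, -2), c(2, 1), c(-1, -3)), a)
  expect_error(looping_angle(c(1, 1), c(1, 1), c(0, 1)), "coincide")
  expect_error(looping_angle(c(0, 0), c(1, 1), c(0, 0)), "zero")
})
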