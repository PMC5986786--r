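test_that("line profiles on constant and gradient images", {
  g <- pixel_grid(matrix(7, 60, 80), 0.5, "intensity")
  path <- rbind(c(5, 15), c(35, 15))
  pr <- line_profile(g, path, width_px = 10)
  expect_true(all(abs(pr$raw - 7) < 1e-12))
  # pure vertical gradient, horizontal path: perpendicular averaging is
  # symmetric, so the profile stays constant
  gv <- pixel_grid(matrix(rep(seq_len(60), 80), 60, 80), 0.5, "intensity")
  pr2 <- line_profile(gv, path, width_px = 10)
  expect_lt(diff(range(pr2$raw)), 1e-9)
})

test_that("profile of a Gaussian ridge matches a supersampled oracle", {
  px <- 0.5
  nr <- 80; nc <- 120
  # ridge along y = 20 um with amplitude varying along x
  colx <- (seq_len(nc) - 0.5) * px
  rowy <- (nr - seq_len(nr) + 0.5) * px
  amp <- function(x) 100 + 60 * sin(x / 8)
  img <- outer(rowy, colx, function(y, x) amp(x) * exp(-(y - 20)^2 / (2 * 1^2)))
  g <- pixel_grid(img, px, "intensity")
  path <- rbind(c(10, 20), c(50, 20))
  pr <- line_profile(g, path, width_px = 10)
  # oracle: dense numeric integration of the analytic field over the width
  oracle <- vapply(pr$arc_um, function(s) {
    x <- 10 + s
    offs <- seq(-4.5, 4.5, length.out = 10) * px
    ys <- 20 + offs
    mean(amp(x) * exp(-(ys - 20)^2 / 2))
  }, numeric(1))
  expect_true(all(abs(pr$raw - oracle) / oracle < 0.01))
})

test_that("min-max normalisation is exact and affine invariant", {
  expect_equal(minmax_normalise(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(1)
  v <- runif(50, 10, 200)
  expect_equal(minmax_normalise(3.7 * v + 12), minmax_normalise(v),
               tolerance = 1e-12)
  expect_error(minmax_normalise(rep(5, 10)), "dynamic range")
  nv <- minmax_normalise(v)
  expect_equal(sum(nv == 0), 1)
  expect_equal(sum(nv == 1), 1)
})

test_that("apical accumulation calls follow the margin rule", {
  mk <- function(vals) {
    d <- data.frame(arc_um = seq_along(vals) - 1, raw = vals)
    class(d) <- c("intensity_profile", "data.frame")
    d
  }
  ap <- mk(c(0, 100, rep(100, 10)))
  ba <- mk(c(0, 100, rep(0, 10)))
  expect_true(apical_accumulation_call(ap, ba, c(2, 11))$aa)
  expect_false(apical_accumulation_call(ap, ap, c(2, 11))$aa)
  expect_error(apical_accumulation_call(ap, ba, c(50, 60)), "empty OFT")
})

test_that("ventricular mean intensity normalises a cohort as defined", {
  px <- 1
  mk_heart <- function(amp) {
    img <- matrix(10, 40, 40)          # background level 10
    img[10:25, 10:25] <- 10 + amp      # ventricle
    pixel_grid(img, px, "intensity")
  }
  roi <- matrix(FALSE, 40, 40); roi[10:25, 10:25] <- TRUE
  bg <- matrix(FALSE, 40, 40); bg[30:38, 30:38] <- TRUE
  amps <- c(20, 40, 80)
  v <- vapply(amps, function(a)
    ventricular_mean_intensity(mk_heart(a), roi, bg)$v, numeric(1))
  nv <- normalise_cohort(v)
  expect_equal(nv, amps / mean(amps), tolerance = 1e-9)
  # identical hearts: all ones
  v2 <- rep(v[1], 5)
  expect_equal(normalise_cohort(v2), rep(1, 5))
  # background equals signal: zero
  flat <- pixel_grid(matrix(10, 40, 40), px, "intensity")
  expect_equal(ventricular_mean_intensity(flat, roi, bg)$v, 0)
})

test_that("co-localisation arithmetic reproduces printed-count percentages", {
  # 20 of 41 transitions positive in both channels -> 49 percent
  pres <- data.frame(presence_A = rep(TRUE, 41),
                     presence_B = c(rep(TRUE, 20), rep(FALSE, 21)))
  expect_equal(coloc_table(pres)$percent, 49)
  # 10 of 15 -> 67 percent
  pres2 <- data.frame(presence_A = rep(TRUE, 15),
                      presence_B = c(rep(TRUE, 10), rep(FALSE, 5)))
  expect_equal(coloc_table(pres2)$percent, 67)
  # permutation invariance over transition-state ordering
  set.seed(4)
  perm <- sample(41)
  expect_equal(coloc_table(pres[perm, ])$percent, 49)
})

test_that("presence at a transition state uses the k-sigma background rule", {
  px <- 0.5
  set.seed(6)
  base <- matrix(rnorm(100 * 100, 20, 2), 100, 100)
  bright <- base
  # bright spots at two vertices, dim at one
  spot <- function(m, x, y, amp) {
    cc <- round(x / px); rr <- round(100 - y / px)
    m[(rr - 2):(rr + 2), (cc - 2):(cc + 2)] <-
      m[(rr - 2):(rr + 2), (cc - 2):(cc + 2)] + amp
    m
  }
  chA <- spot(spot(spot(base, 10, 10, 50), 25, 25, 50), 40, 40, 50)
  chB <- spot(spot(base, 10, 10, 50), 25, 25, 50)  # absent at third
  ts <- data.frame(ts_id = 1:3, x_um = c(10, 25, 40), y_um = c(10, 25, 40))
  bg <- matrix(FALSE, 100, 100); bg[80:95, 80:95] <- TRUE
  ct <- colocalisation_at_ts(ts, pixel_grid(chA, px, "intensity"),
                             pixel_grid(chB, px, "intensity"),
                             background = bg, radius_um = 1.5, k_sigma = 2)
  expect_equal(ct$table$presence_A, c(TRUE, TRUE, TRUE))
  expect_equal(ct$table$presence_B, c(TRUE, TRUE, FALSE))
  expect_equal(ct$n_coloc, 2)
  expect_equal(ct$percent, 67)
})

test_that("wider averaging never increases noise variance (statistically)", {
  set.seed(9)
  vr <- matrix(NA_real_, 20, 2)
  for (i in 1:20) {
    g <- pixel_grid(matrix(rnorm(60 * 80, 50, 5), 60, 80), 0.5, "intensity")
    path <- rbind(c(5, 15), c(35, 15))
    vr[i, 1] <- stats::var(line_profile(g, path, width_px = 2)$raw)
    vr[i, 2] <- stats::var(line_profile(g, path, width_px = 10)$raw)
  }
  expect_lt(mean(vr[, 2]), mean(vr[, 1]))
})
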