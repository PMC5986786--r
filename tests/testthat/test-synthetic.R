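test_that("generation is fully deterministic under (spec, seed)", {
  spec <- synthetic_spec()
  a <- generate_tissue(spec, seed = 5)
  b <- generate_tissue(spec, seed = 5)
  expect_identical(a$labels$values, b$labels$values)
  expect_identical(a$truth$ts, b$truth$ts)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_equal(a$truth$spec_hash, b$truth$spec_hash)
  c2 <- generate_tissue(spec, seed = 6)
  expect_false(identical(a$labels$values, c2$labels$values))
})

test_that("emitted artefacts are consistent: mesh, raster, truth", {
  tis <- cached_tissue(2)
  # mesh cells match raster labels
  labs <- sort(unique(as.vector(tis$labels$values)))
  labs <- labs[labs > 0]
  expect_setequal(cell_ids(tis$mesh), labs)
  expect_setequal(tis$truth$cells$cell_id, labs)
  # transition manifest equals detection on the emitted mesh
  det <- detect_transition_states(tis$mesh)
  expect_equal(det$order, tis$truth$ts$order)
  expect_equal(nrow(det), tis$truth$n_ts_injected + tis$truth$n_ts_incidental)
})

test_that("cell counts land in the intended range and regions are covered", {
  tis <- cached_tissue(1)
  n <- length(tis$mesh$cells)
  expect_gte(n, 60); expect_lte(n, 300)
  regs <- table(tis$truth$cells$region)
  expect_setequal(names(regs), c("IC", "OFT", "OC_near_OFT", "OC_middle",
                                 "OC_near_AV", "AV"))
  expect_true(all(regs >= 3))
})

test_that("transition rate control tracks the requested rate across seeds", {
  rate <- 9
  got <- vapply(1:5, function(sd) {
    tis <- cached_tissue(sd, synthetic_spec(ts_rate_per_100 = rate))
    ts_frequency(tis$mesh, exclude_boundary_cells = FALSE)$ts_per_100
  }, numeric(1))
  # injected counts are rounded to whole transitions: allow 1.5 per 100
  expect_lt(abs(mean(got) - rate), 1.5)
})

test_that("zero-noise uniform-amplitude channels give flat membrane profiles", {
  tis <- cached_tissue(1)
  spec <- synthetic_spec()
  spec$channels$A$amp[] <- 150
  spec$channels$A$noise_sd <- 0
  spec$channels$B$amp[] <- 150
  spec$channels$B$noise_sd <- 0
  ch <- generate_channels(tis, spec, seed = 3)
  # profile along a shared cell boundary: constant amplitude. Pick the
  # longest adjacency whose both endpoint vertices are junctions.
  adj <- tis$mesh$adjacency[order(-tis$mesh$adjacency$shared_um), ]
  v1 <- NULL
  for (r in seq_len(nrow(adj))) {
    ends <- NULL
    for (v in tis$mesh$vertices) {
      if (all(c(adj$cell_a[r], adj$cell_b[r]) %in% v$incident_cells))
        ends <- rbind(ends, v$position)
    }
    if (!is.null(ends) && nrow(ends) == 2) { v1 <- ends; break }
  }
  skip_if(is.null(v1), "no two-vertex edge found")
  # trim endpoints: junction corners mix three membranes
  mid <- (v1[1, ] + v1[2, ]) / 2
  a <- mid + 0.7 * (v1[1, ] - mid); b <- mid + 0.7 * (v1[2, ] - mid)
  pr <- line_profile(ch$A, rbind(a, b), width_px = 8)
  expect_lt(stats::sd(pr$raw) / mean(pr$raw), 0.1)
  # and the peak equals the injected amplitude
  expect_equal(max(ch$A$values), 150, tolerance = 1e-6)
})

test_that("channel-B suppression at transition states injects a known co-localisation fraction", {
  spec <- synthetic_spec(ts_rate_per_100 = 9)
  spec$channels$suppress_B_fraction <- 0.5
  tis <- cached_tissue(3, synthetic_spec(ts_rate_per_100 = 9))
  ch <- generate_channels(tis, spec, seed = 7)
  ts <- detect_transition_states(tis$mesh)
  skip_if(nrow(ts) < 4, "too few transition states in fixture")
  bg <- tis$labels$values == 0L  # background mask: outside the band
  ct <- colocalisation_at_ts(ts, ch$A, ch$B, background = bg,
                             radius_um = 1.5, k_sigma = 2)
  n_sup <- length(ch$truth$suppressed_ts)
  expect_equal(ct$n_total - ct$n_coloc, n_sup)
  expect_equal(sort(ts$ts_id[!ct$table$presence_B]),
               sort(ch$truth$suppressed_ts))
})

test_that("mid-sagittal fixture recovers the injected apical-basal gradient", {
  ms <- generate_midsagittal(delta = 0.4, seed = 2, noise_sd = 0)
  ap <- line_profile(ms$channel, ms$apical_path, width_px = 10,
                     side = "apical")
  ba <- line_profile(ms$channel, ms$basal_path, width_px = 10,
                     side = "basal")
  call <- apical_accumulation_call(ap, ba, ms$oft_window, margin = 0.2)
  expect_true(call$aa)
  expect_equal(call$delta, 0.4, tolerance = 0.06)
  # no injected difference: no call
  ms0 <- generate_midsagittal(delta = 0, seed = 2, noise_sd = 0)
  ap0 <- line_profile(ms0$channel, ms0$apical_path, width_px = 10)
  ba0 <- line_profile(ms0$channel, ms0$basal_path, width_px = 10)
  call0 <- apical_accumulation_call(ap0, ba0, ms0$oft_window, margin = 0.2)
  expect_false(call0$aa)
  expect_lt(abs(call0$delta), 0.05)
  # determinism
  ms2 <- generate_midsagittal(delta = 0.4, seed = 2, noise_sd = 0)
  expect_identical(ms$channel$values, ms2$channel$values)
})

test_that("statistical faithfulness: measured means track spec values", {
  sh_all <- NULL
  for (sd in 1:3) {
    tis <- cached_tissue(sd)
    sh <- measure_cells(tis$mesh)
    sh$region <- tis$truth$cells$region[match(sh$cell_id,
                                              tis$truth$cells$cell_id)]
    sh_all <- rbind(sh_all, sh)
  }
  oc <- grepl("^OC", sh_all$region); ic <- sh_all$region == "IC"
  expect_equal(mean(sh_all$area_um2[oc]), 107, tolerance = 0.05)
  expect_equal(mean(sh_all$area_um2[ic]), 83, tolerance = 0.05)
  expect_lt(abs(mean(sh_all$circularity[oc]) - 0.53), 0.05)
  expect_lt(abs(mean(sh_all$circularity[ic]) - 0.60), 0.05)
})

test_that("presets encode the intended contrasts", {
  expect_equal(preset_spec("wt")$ts_rate_per_100, 5.5)
  expect_equal(preset_spec("wt26")$ts_rate_per_100, 9.0)
  fz <- preset_spec("fzd7a")
  expect_equal(fz$ts_rate_per_100, 8.8)
  oft <- fz$segments$name == "OFT"
  expect_gt(fz$segments$orientation_sd_deg[oft], 30)
})

test_that("spec validation rejects malformed segment tables", {
  bad <- default_segments <- synthetic_spec()$segments
  bad$name[1] <- "LV"
  expect_error(synthetic_spec(segments = bad), "named exactly")
  bad2 <- synthetic_spec()$segments
  bad2$area_sd[2] <- -1
  expect_error(synthetic_spec(segments = bad2), "variances")
})
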