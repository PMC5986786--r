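# Synthetic intensity channels: membrane-localised signal with per-segment
# (and, for mid-sagittal fixtures, per-side) amplitudes, Gaussian
# cross-section (sigma = 1 px), additive Gaussian noise, clipped to the bit
# depth.

# distance (in pixels) from every pixel centre to the nearest membrane
# pixel, up to max_d; Inf beyond. Membrane pixels are pixels with a
# 4-neighbour of a different label (including background).
membrane_distance_px <- function(labm, max_d = 3) {
  nr <- nrow(labm); nc <- ncol(labm)
  up <- rbind(labm[1, ], labm[-nr, , drop = FALSE])
  dn <- rbind(labm[-1, , drop = FALSE], labm[nr, ])
  lf <- cbind(labm[, 1], labm[, -nc, drop = FALSE])
  rt <- cbind(labm[, -1, drop = FALSE], labm[, nc])
  memb <- (labm != up) | (labm != dn) | (labm != lf) | (labm != rt)
  d <- matrix(Inf, nr, nc)
  d[memb] <- 0
  rng <- ceiling(max_d)
  offs <- expand.grid(dr = -rng:rng, dc = -rng:rng)
  offs$dist <- sqrt(offs$dr^2 + offs$dc^2)
  offs <- offs[offs$dist > 0 & offs$dist <= max_d, ]
  offs <- offs[order(offs$dist), ]
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    shifted <- matrix(FALSE, nr, nc)
    shifted[rs, cs] <- memb[rs + dr, cs + dc]
    d[shifted & d > offs$dist[k]] <- offs$dist[k]
  }
  d
}

#' Generate two membrane-intensity channels for a synthetic tissue
#'
#' Signal is membrane-localised with a Gaussian cross-section (sigma =
#' 1 px) and a per-segment amplitude taken from the spec's channel model;
#' additive Gaussian noise is applied and values are clipped to the bit
#' depth. Optionally, channel B is silenced within a small disc around a
#' random fraction of the tissue's transition states, which injects a known
#' co-localisation fraction.
#'
#' @param tissue result of [generate_tissue()].
#' @param spec the `synthetic_spec` used to generate the tissue.
#' @param seed RNG seed (noise and the suppressed-TS draw).
#' @return list with `A`, `B` (intensity `pixel_grid`s) and `truth`
#'   (per-channel amplitudes, suppressed transition-state ids, seed).
#' @export
generate_channels <- function(tissue, spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, function() generate_channels_impl(tissue, spec, seed))
}

generate_channels_impl <- function(tissue, spec, seed) {
  labm <- tissue$labels$values
  px <- tissue$labels$pixel_size
  ch <- spec$channels
  bit_max <- 2^(ch$bit_depth %||% 8L) - 1
  d <- membrane_distance_px(labm, max_d = 4)
  prof <- exp(-d^2 / 2)                       # sigma = 1 px
  prof[!is.finite(prof)] <- 0
  # per-pixel amplitude from the segment of the owning cell
  reg <- tissue$truth$cells$region[match(as.vector(labm),
                                         tissue$truth$cells$cell_id)]
  mk_chan <- function(amp, noise_sd) {
    a <- amp[reg]
    a[is.na(a)] <- 0
    base <- matrix(a, nrow(labm), ncol(labm)) * prof
    base
  }
  A <- mk_chan(ch$A$amp, ch$A$noise_sd)
  B <- mk_chan(ch$B$amp, ch$B$noise_sd)
  sup_frac <- ch$suppress_B_fraction %||% 0
  sup_ids <- integer(0)
  ts <- tissue$truth$ts
  if (sup_frac > 0 && nrow(ts) > 0) {
    k <- round(sup_frac * nrow(ts))
    if (k > 0) {
      sup_ids <- sort(sample(ts$ts_id, k))
      nr <- nrow(labm)
      rad_px <- ceiling(2 / px)               # silence within 2 um
      for (id in sup_ids) {
        i <- which(ts$ts_id == id)
        c0 <- ts$x_um[i] / px + 0.5; r0 <- nr - ts$y_um[i] / px + 0.5
        rows <- max(1, floor(r0 - rad_px)):min(nr, ceiling(r0 + rad_px))
        cols <- max(1, floor(c0 - rad_px)):min(ncol(labm), ceiling(c0 + rad_px))
        rr <- matrix(rows, length(rows), length(cols))
        cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
        disc <- (rr - r0)^2 + (cc - c0)^2 <= rad_px^2
        sub <- B[rows, cols]
        sub[disc] <- 0
        B[rows, cols] <- sub
      }
    }
  }
  finish <- function(m, noise_sd) {
    m <- m + stats::rnorm(length(m), 0, noise_sd)
    m[m < 0] <- 0; m[m > bit_max] <- bit_max
    pixel_grid(matrix(m, nrow(labm), ncol(labm)), px, "intensity")
  }
  list(A = finish(A, ch$A$noise_sd), B = finish(B, ch$B$noise_sd),
       truth = list(amp_A = ch$A$amp, amp_B = ch$B$amp,
                    suppressed_ts = sup_ids, seed = seed))
}

#' Generate a mid-sagittal two-membrane fixture
#'
#' Two nested open arcs (apical outside, basal inside) run from the
#' atrio-ventricular end to the outflow-tract end of the heart tube. Both
#' membranes carry the same channel signal except for a controlled
#' apical-minus-basal amplitude difference `delta` (on the normalised
#' scale) inside the outflow-tract window, which is the quantity the
#' apical-accumulation call estimates. The basal amplitude profile anchors
#' the joint min-max normalisation: it starts at the low amplitude, peaks
#' at the high amplitude early in the arc, and plateaus at mid-level
#' through the window.
#'
#' @param delta injected apical-minus-basal normalised difference in the
#'   OFT window (0 to ~0.5).
#' @param seed RNG seed.
#' @param noise_sd additive Gaussian noise (grey values).
#' @param amp_range low/high raw amplitudes (grey values).
#' @param radius_um outer (apical) arc radius.
#' @param gap_um distance between apical and basal membranes.
#' @param pixel_size um per pixel.
#' @param bit_depth 8 or 16.
#' @return list with `channel` (intensity `pixel_grid`), `apical_path`,
#'   `basal_path` (n x 2 um matrices), `oft_window` (arc interval, um, on
#'   each path's own arc length), and `truth`.
#' @export
generate_midsagittal <- function(delta = 0.3, seed = 1L, noise_sd = 2,
                                 amp_range = c(30, 200), radius_um = 40,
                                 gap_um = 4, pixel_size = 0.2,
                                 bit_depth = 8L) {
  with_seed(seed, function() {
    px <- pixel_size
    bit_max <- 2^bit_depth - 1
    # arcs from angle 200 deg (AV end) sweeping 250 deg to the OFT end
    th0 <- deg2rad(200); sweep <- deg2rad(250)
    ctr <- c(radius_um + 6, radius_um + 6)
    n_half <- ceiling(radius_um * sweep / px) + 1
    th <- th0 + seq(0, sweep, length.out = n_half)
    apical <- cbind(ctr[1] + radius_um * cos(th),
                    ctr[2] + radius_um * sin(th))
    basal <- cbind(ctr[1] + (radius_um - gap_um) * cos(th),
                   ctr[2] + (radius_um - gap_um) * sin(th))
    t01 <- seq(0, 1, length.out = n_half)
    lo <- amp_range[1]; hi <- amp_range[2]
    base_shape <- function(t) {
      # 0 at t = 0, 1 at t = 0.15, 0.4 plateau from t = 0.4 on
      ifelse(t < 0.15, t / 0.15,
             ifelse(t < 0.4, 1 - 0.6 * (t - 0.15) / 0.25, 0.4))
    }
    oft_t <- c(0.6, 0.9)
    amp_basal <- lo + (hi - lo) * base_shape(t01)
    amp_apical <- amp_basal +
      (hi - lo) * delta * (t01 >= oft_t[1] & t01 <= oft_t[2])
    nr <- ceiling(2 * (radius_um + 6) / px)
    ncn <- nr
    img <- matrix(0, nr, ncn)
    img <- splat_ridge(img, px, apical, amp_apical)
    img <- splat_ridge(img, px, basal, amp_basal)
    img <- img + stats::rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0; img[img > bit_max] <- bit_max
    arc_len <- radius_um * sweep
    arc_len_b <- (radius_um - gap_um) * sweep
    list(channel = pixel_grid(matrix(img, nr, ncn), px, "intensity"),
         apical_path = apical, basal_path = basal,
         oft_window = oft_t * arc_len,
         oft_window_basal = oft_t * arc_len_b,
         truth = list(delta = delta, amp_range = amp_range,
                      oft_t = oft_t, noise_sd = noise_sd, seed = seed))
  })
}

# draw a ridge of amplitude amp(t) along a path by max-splatting Gaussian
# stamps (sigma = 1 px). The Gaussian is evaluated at the true sub-pixel
# distance between each pixel centre and the path sample, so the ridge
# cross-section is an honest Gaussian tube; the path is resampled to
# half-pixel spacing to suppress along-path scalloping.
splat_ridge <- function(img, px, path, amp) {
  nr <- nrow(img); ncn <- ncol(img)
  # resample path + amplitude to ~0.5 px spacing
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                         path[-nrow(path), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[length(cum)], by = px / 2)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(path) - 1)
  w <- (s - cum[i]) / pmax(seg[i], 1e-300)
  pts <- path[i, , drop = FALSE] + (path[i + 1, , drop = FALSE] -
                                      path[i, , drop = FALSE]) * w
  av <- amp[i] + (amp[i + 1] - amp[i]) * w
  stamp_r <- 4L
  dgrid <- expand.grid(dr = -stamp_r:stamp_r, dc = -stamp_r:stamp_r)
  for (k in seq_along(s)) {
    rf <- nr - pts[k, 2] / px + 0.5   # fractional row of the sample
    cf <- pts[k, 1] / px + 0.5
    r0 <- round(rf); c0 <- round(cf)
    rr <- r0 + dgrid$dr; cc <- c0 + dgrid$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncn
    d2 <- (rr[ok] - rf)^2 + (cc[ok] - cf)^2
    idx <- cbind(rr[ok], cc[ok])
    img[idx] <- pmax(img[idx], av[k] * exp(-d2 / 2))
  }
  img
}
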