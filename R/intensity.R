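# Membrane fluorescence analysis: width-averaged line profiles along apical
# and basal membrane paths, min-max normalisation, apical-accumulation
# calls, ventricular mean intensity, and two-channel presence calls at
# transition states.

#' Width-averaged line profile along a path
#'
#' The path is resampled at one-pixel arc spacing; at every sample the value
#' is the mean of `width_px` bilinear samples placed symmetrically along the
#' local perpendicular (one-pixel spacing across the width), averaging out
#' noise like a wide line scan. Samples whose full width leaves the raster
#' are clipped with a warning.
#'
#' @param channel a `pixel_grid` of kind "intensity".
#' @param path n x 2 matrix of path points (um, y-up).
#' @param width_px averaging width in pixels, >= 1.
#' @param side optional label ("apical"/"basal") carried into the result.
#' @return an `intensity_profile`: data.frame `arc_um`, `raw` plus
#'   attributes `side`, `width_px`, `pixel_size`.
#' @export
line_profile <- function(channel, path, width_px = 10, side = NA_character_) {
  stopifnot(inherits(channel, "pixel_grid"))
  if (width_px < 1) stopf("width_px must be >= 1")
  path <- matrix(as.numeric(as.matrix(path)), ncol = 2)
  if (nrow(path) < 2) stopf("path needs >= 2 points")
  px <- channel$pixel_size
  seg <- sqrt(rowSums((path[-1, , drop = FALSE] -
                         path[-nrow(path), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) stopf("zero-length path")
  cum <- c(0, cumsum(seg))
  s <- seq(0, L, by = px)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(path) - 1)
  w <- (s - cum[i]) / pmax(seg[i], 1e-300)
  pts <- path[i, , drop = FALSE] + (path[i + 1, , drop = FALSE] -
                                      path[i, , drop = FALSE]) * w
  dirs <- path[i + 1, , drop = FALSE] - path[i, , drop = FALSE]
  dn <- sqrt(rowSums(dirs^2))
  dirs <- dirs / dn
  perp <- cbind(-dirs[, 2], dirs[, 1])
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * px
  acc <- matrix(NA_real_, length(s), width_px)
  for (k in seq_len(width_px)) {
    q <- pts + perp * offs[k]
    rc <- grid_rc(channel, q[, 1], q[, 2])
    acc[, k] <- bilinear_sample(channel$values, rc[, 1], rc[, 2])
  }
  vals <- rowMeans(acc)
  if (anyNA(vals)) {
    warnf("%d profile sample(s) left the raster and were clipped",
          sum(is.na(vals)))
    keep <- !is.na(vals)
    s <- s[keep]; vals <- vals[keep]
  }
  out <- data.frame(arc_um = s, raw = vals)
  attr(out, "side") <- side
  attr(out, "width_px") <- width_px
  attr(out, "pixel_size") <- px
  class(out) <- c("intensity_profile", "data.frame")
  out
}

#' Min-max normalise a profile
#'
#' Affine map sending the minimum of the selection to 0 and the maximum to
#' 1 (the display normalisation used for single line plots).
#'
#' @param profile an `intensity_profile` (or numeric vector).
#' @return the profile with a `normalised` column (or the normalised
#'   vector).
#' @export
minmax_normalise <- function(profile) {
  v <- if (is.data.frame(profile)) profile$raw else as.numeric(profile)
  rng <- range(v)
  if (rng[2] <= rng[1]) stopf("no dynamic range: flat profile")
  nv <- (v - rng[1]) / (rng[2] - rng[1])
  if (is.data.frame(profile)) {
    profile$normalised <- nv
    profile
  } else nv
}

# joint min-max over two raw profiles so the two sides stay comparable
joint_normalise <- function(a, b) {
  rng <- range(c(a$raw, b$raw))
  if (rng[2] <= rng[1]) stopf("no dynamic range: flat profiles")
  a$normalised <- (a$raw - rng[1]) / (rng[2] - rng[1])
  b$normalised <- (b$raw - rng[1]) / (rng[2] - rng[1])
  list(apical = a, basal = b)
}

#' Apical-accumulation call from paired membrane profiles
#'
#' Both profiles are normalised jointly (one min-max over the two raw
#' selections, so the sides remain comparable); apical accumulation is
#' called when the mean apical minus mean basal normalised intensity inside
#' the outflow-tract window exceeds `margin`. The fixed margin makes the
#' otherwise visual call reproducible.
#'
#' @param apical_prof,basal_prof `intensity_profile`s on a shared raw scale.
#' @param oft_window length-2 arc interval (um) flagged as OFT.
#' @param margin decision margin on the normalised scale, default 0.2.
#' @return an `accumulation_call`: `aa` (logical), `delta` (mean apical -
#'   basal in the window), `margin_used`, `oft_window`.
#' @export
apical_accumulation_call <- function(apical_prof, basal_prof, oft_window,
                                     margin = 0.2) {
  stopifnot(length(oft_window) == 2)
  nb <- joint_normalise(apical_prof, basal_prof)
  ina <- nb$apical$arc_um >= oft_window[1] & nb$apical$arc_um <= oft_window[2]
  inb <- nb$basal$arc_um >= oft_window[1] & nb$basal$arc_um <= oft_window[2]
  if (!any(ina) || !any(inb)) stopf("empty OFT window")
  delta <- mean(nb$apical$normalised[ina]) - mean(nb$basal$normalised[inb])
  structure(list(aa = delta > margin, delta = delta, margin_used = margin,
                 oft_window = oft_window),
            class = "accumulation_call")
}

#' @export
print.accumulation_call <- function(x, ...) {
  cat(sprintf("Apical accumulation: %s (delta = %.3f, margin = %.2f)\n",
              if (x$aa) "yes" else "no", x$delta, x$margin_used))
  invisible(x)
}

#' Ventricular mean intensity, background-subtracted and size-adjusted
#'
#' Per heart: `v = (mean(channel | roi) - mean(channel | background)) /
#' area(roi)`; cohort normalisation divides by the cohort mean of `v`
#' (see [normalise_cohort()]).
#'
#' @param channel a `pixel_grid`.
#' @param ventricle_roi,background_roi logical masks (same dim as the
#'   channel) or polygons (n x 2 um matrices) selecting disjoint regions.
#' @return list with `v` (size-adjusted background-subtracted mean),
#'   `mean_roi`, `mean_bg`, `area_um2`.
#' @export
ventricular_mean_intensity <- function(channel, ventricle_roi, background_roi) {
  roi <- as_mask(channel, ventricle_roi)
  bg <- as_mask(channel, background_roi)
  if (!any(roi) || !any(bg)) stopf("empty ROI")
  if (any(roi & bg)) stopf("ventricle and background ROIs overlap")
  area <- sum(roi) * channel$pixel_size^2
  v <- (mean(channel$values[roi]) - mean(channel$values[bg])) / area
  list(v = v, mean_roi = mean(channel$values[roi]),
       mean_bg = mean(channel$values[bg]), area_um2 = area)
}

#' Normalise per-heart values by the cohort mean
#' @param v numeric vector of per-heart values.
#' @return `v / mean(v)`.
#' @export
normalise_cohort <- function(v) {
  m <- mean(v)
  if (m == 0) stopf("cohort mean is zero; cannot normalise")
  v / m
}

as_mask <- function(grid, roi) {
  if (is.logical(roi) && is.matrix(roi)) {
    if (!all(dim(roi) == dim(grid$values)))
      stopf("ROI mask dimensions do not match the channel")
    return(roi)
  }
  roi <- as_poly(roi)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  xy <- grid_xy(grid, rc$row, rc$col)
  matrix(points_in_poly(xy[, 1], xy[, 2], roi), nr, nc)
}

#' Two-channel presence calls at transition states
#'
#' A channel is "present" at a transition state when the mean intensity in
#' a disc of `radius_um` around the vertex exceeds the channel background
#' mean by `k_sigma` background standard deviations; co-localisation means
#' presence in both channels. The background is estimated from the supplied
#' mask or polygon per channel.
#'
#' @param ts transition-state table from [detect_transition_states()].
#' @param chanA,chanB co-registered `pixel_grid`s.
#' @param background ROI (mask or polygon) used for background statistics on
#'   both channels.
#' @param radius_um disc radius, default 1.5 um.
#' @param k_sigma threshold in background s.d. units, default 2.
#' @return a `coloc_table`: `table` (data.frame `ts_id, presence_A,
#'   presence_B, coloc`), `n_total`, `n_coloc`, `percent` (rounded half-up
#'   to integer), `settings`.
#' @export
colocalisation_at_ts <- function(ts, chanA, chanB, background,
                                 radius_um = 1.5, k_sigma = 2) {
  stopifnot(inherits(chanA, "pixel_grid"), inherits(chanB, "pixel_grid"))
  if (!all(dim(chanA$values) == dim(chanB$values)) ||
      chanA$pixel_size != chanB$pixel_size)
    stopf("channels are not co-registered")
  if (nrow(ts) == 0) stopf("no transition states supplied")
  bgA <- as_mask(chanA, background); bgB <- bgA
  statA <- c(mean(chanA$values[bgA]), stats::sd(chanA$values[bgA]))
  statB <- c(mean(chanB$values[bgB]), stats::sd(chanB$values[bgB]))
  presence <- function(chan, x, y, thr) {
    rc0 <- grid_rc(chan, x, y)
    rpx <- radius_um / chan$pixel_size
    rows <- round(rc0[1] + seq(-ceiling(rpx), ceiling(rpx)))
    cols <- round(rc0[2] + seq(-ceiling(rpx), ceiling(rpx)))
    rows <- rows[rows >= 1 & rows <= nrow(chan$values)]
    cols <- cols[cols >= 1 & cols <= ncol(chan$values)]
    if (!length(rows) || !length(cols)) stopf("transition state outside raster")
    gg <- expand.grid(row = rows, col = cols)
    d2 <- (gg$row - rc0[1])^2 + (gg$col - rc0[2])^2
    sel <- d2 <= rpx^2
    if (!any(sel)) sel <- d2 == min(d2)
    mean(chan$values[cbind(gg$row[sel], gg$col[sel])]) > thr
  }
  pa <- logical(nrow(ts)); pb <- logical(nrow(ts))
  for (i in seq_len(nrow(ts))) {
    pa[i] <- presence(chanA, ts$x_um[i], ts$y_um[i],
                      statA[1] + k_sigma * statA[2])
    pb[i] <- presence(chanB, ts$x_um[i], ts$y_um[i],
                      statB[1] + k_sigma * statB[2])
  }
  coloc_table(data.frame(ts_id = ts$ts_id, presence_A = pa, presence_B = pb),
              settings = list(radius_um = radius_um, k_sigma = k_sigma))
}

#' Build a co-localisation table from presence records
#'
#' The count-to-percent arithmetic used for reporting: co-localised means
#' present in both channels; percent is `100 * n_coloc / n_total` rounded
#' half-up to integer.
#'
#' @param presence data.frame with logical columns `presence_A`,
#'   `presence_B` (and optionally `ts_id`).
#' @param settings optional list recorded alongside.
#' @return a `coloc_table`.
#' @export
coloc_table <- function(presence, settings = list()) {
  stopifnot(all(c("presence_A", "presence_B") %in% names(presence)))
  presence$coloc <- presence$presence_A & presence$presence_B
  n <- nrow(presence)
  k <- sum(presence$coloc)
  structure(list(table = presence, n_total = n, n_coloc = k,
                 percent = round_half_up(100 * k / n),
                 settings = settings),
            class = "coloc_table")
}

#' @export
print.coloc_table <- function(x, ...) {
  cat(sprintf("Co-localisation at transition states: %d/%d = %d%%\n",
              x$n_coloc, x$n_total, x$percent))
  invisible(x)
}
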