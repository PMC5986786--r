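# Synthetic bean-shaped epithelium generator. Emulates the statistical
# structure the analysis assumes: a single-layered band of polygonal cells
# along a Fourier-perturbed elliptical outline, with region-dependent cell
# area, circularity and axial orientation, a controllable transition-state
# rate, and (separately) two membrane-intensity channels. Every output is
# deterministic under (spec, seed) and accompanied by a ground-truth
# manifest.

#' Specification for a synthetic epithelium
#'
#' Defaults describe a wild-type-like two-chambered-stage ventricle: outer
#' curvature cells large and elongated (area 107 um^2, circularity 0.53),
#' inner curvature cells small and round (83 um^2, 0.6), inner/outer
#' curvature cells oriented radially (0 degrees to the outline normal),
#' outflow-tract and atrio-ventricular cells circumferentially (90 degrees),
#' and 5.5 transition states per 100 cells.
#'
#' @param outline_semi_axes ellipse semi-axes (um).
#' @param outline_harmonics list of harmonic perturbations of the outline
#'   radius, each `c(k, amp_um, phase_rad)` (at most 3).
#' @param band_width epithelial band width in projection (um).
#' @param pixel_size um per pixel of the emitted rasters.
#' @param landmark_angles_deg polar angles (CCW from +x, about the ellipse
#'   centre) of surface landmarks 1-4 on the outline.
#' @param segments data.frame with one row per segment (`name`,
#'   `area_mean`, `area_sd`, `circularity`, `orientation_mean_deg`,
#'   `orientation_sd_deg`); names must be the six canonical segment names.
#' @param ts_rate_per_100 target transition states per 100 cells.
#' @param ts_order order of injected transition states (4 = T1; larger
#'   values give rosettes).
#' @param channels list with elements `A` and `B`, each
#'   `list(amp = <named per-segment amplitude>, noise_sd = <grey>)`, plus
#'   optional `suppress_B_fraction` (fraction of transition states at which
#'   channel B is silenced) and `bit_depth` (8 or 16).
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(outline_semi_axes = c(85, 55),
                           outline_harmonics = list(c(2, 5, 0.6),
                                                    c(3, 3, 2.1)),
                           band_width = 28,
                           pixel_size = 0.2,
                           landmark_angles_deg = c(lm1 = 210, lm2 = 285,
                                                   lm3 = 330, lm4 = 160),
                           segments = default_segments(),
                           ts_rate_per_100 = 5.5,
                           ts_order = 4L,
                           channels = default_channels()) {
  segments <- as.data.frame(segments)
  need <- c("name", "area_mean", "area_sd", "circularity",
            "orientation_mean_deg", "orientation_sd_deg")
  if (!all(need %in% names(segments)))
    stopf("segments needs columns: %s", paste(need, collapse = ", "))
  if (!setequal(segments$name, SEGMENT_NAMES))
    stopf("segments must be named exactly: %s",
          paste(SEGMENT_NAMES, collapse = ", "))
  if (any(segments$area_sd < 0) || any(segments$orientation_sd_deg < 0))
    stopf("variances must be >= 0")
  if (ts_rate_per_100 < 0) stopf("ts_rate_per_100 must be >= 0")
  if (length(outline_harmonics) > 3) stopf("at most 3 outline harmonics")
  spec <- list(outline_semi_axes = as.numeric(outline_semi_axes),
               outline_harmonics = outline_harmonics,
               band_width = band_width, pixel_size = pixel_size,
               landmark_angles_deg = landmark_angles_deg,
               segments = segments,
               ts_rate_per_100 = ts_rate_per_100,
               ts_order = as.integer(ts_order),
               channels = channels)
  class(spec) <- "synthetic_spec"
  spec
}

default_segments <- function() {
  data.frame(name = SEGMENT_NAMES,
             area_mean = c(83, 95, 107, 107, 107, 95),
             area_sd = c(15, 18, 20, 20, 20, 18),
             circularity = c(0.60, 0.57, 0.53, 0.53, 0.53, 0.57),
             orientation_mean_deg = c(0, 90, 0, 0, 0, 90),
             orientation_sd_deg = c(20, 15, 20, 20, 20, 15))
}

default_channels <- function() {
  amp_polar <- c(IC = 120, OFT = 220, OC_near_OFT = 200, OC_middle = 160,
                 OC_near_AV = 120, AV = 100)
  list(A = list(amp = amp_polar, noise_sd = 4),
       B = list(amp = amp_polar, noise_sd = 4),
       suppress_B_fraction = 0,
       bit_depth = 8L)
}

#' Preset synthetic specifications
#'
#' `"wt"`: wild-type-like 54 hpf regime (the [synthetic_spec()] defaults,
#' 5.5 transition states per 100 cells). `"wt26"`: heart-tube stage with
#' 9.0 per 100 cells. `"fzd7a"`: PCP-deficient-like regime (8.8 per 100
#' cells, outflow-tract orientation shifted and dispersed). `"oft90"`: an
#' orientation-recovery benchmark ring whose outflow-tract sector dominates
#' the band (about 86 cells at mean axial angle 90 degrees, angular s.d.
#' 15 degrees).
#'
#' @param name preset name.
#' @return a `synthetic_spec`.
#' @export
preset_spec <- function(name = c("wt", "wt26", "fzd7a", "oft90")) {
  name <- match.arg(name)
  switch(name,
         wt = synthetic_spec(),
         wt26 = synthetic_spec(ts_rate_per_100 = 9.0),
         fzd7a = {
           seg <- default_segments()
           oft <- seg$name == "OFT"
           seg$orientation_mean_deg[oft] <- 118.4 - 90
           seg$orientation_sd_deg[oft] <- 35
           synthetic_spec(segments = seg, ts_rate_per_100 = 8.8)
         },
         oft90 = {
           seg <- default_segments()
           seg$area_mean <- c(95, 81, 95, 95, 95, 95)
           seg$circularity <- c(0.57, 0.55, 0.57, 0.57, 0.57, 0.57)
           seg$orientation_mean_deg <- c(0, 90, 0, 0, 0, 90)
           seg$orientation_sd_deg <- c(20, 15, 20, 20, 20, 15)
           synthetic_spec(landmark_angles_deg = c(lm1 = 350, lm2 = 0,
                                                  lm3 = 310, lm4 = 330),
                          segments = seg, ts_rate_per_100 = 0)
         })
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec: ellipse %g x %g um, band %g um, %g TS/100 cells, %g um/px>\n",
              x$outline_semi_axes[1], x$outline_semi_axes[2], x$band_width,
              x$ts_rate_per_100, x$pixel_size))
  invisible(x)
}

# deterministic 31-bit polynomial hash of the serialised spec
spec_hash <- function(spec) {
  s <- as.character(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE,
                                     digits = NA, force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# run fn() under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# outline radius at polar angle theta (radians) about the ellipse centre
outline_radius <- function(spec, theta) {
  a <- spec$outline_semi_axes[1]; b <- spec$outline_semi_axes[2]
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  for (h in spec$outline_harmonics) r <- r + h[2] * cos(h[1] * theta + h[3])
  r
}

# outline geometry shared by the generator: raster frame, traced outline,
# landmarks, smoothed outline and segment partition
synthetic_frame <- function(spec, n_trace = 24) {
  amp <- sum(vapply(spec$outline_harmonics, function(h) abs(h[2]), numeric(1)))
  margin <- 4
  half_w <- spec$outline_semi_axes[1] + amp + margin
  half_h <- spec$outline_semi_axes[2] + amp + margin
  px <- spec$pixel_size
  nc <- 2 * ceiling(half_w / px)
  nr <- 2 * ceiling(half_h / px)
  ctr <- c(nc * px / 2, nr * px / 2)
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  dense <- cbind(ctr[1] + outline_radius(spec, th) * cos(th),
                 ctr[2] + outline_radius(spec, th) * sin(th))
  th_tr <- seq(0, 2 * pi, length.out = n_trace + 1)[-(n_trace + 1)]
  trace <- traced_outline(cbind(ctr[1] + outline_radius(spec, th_tr) * cos(th_tr),
                                ctr[2] + outline_radius(spec, th_tr) * sin(th_tr)))
  smoothed <- smooth_outline(trace)
  la <- deg2rad(spec$landmark_angles_deg)
  lm <- cbind(ctr[1] + outline_radius(spec, la) * cos(la),
              ctr[2] + outline_radius(spec, la) * sin(la))
  landmarks <- place_landmarks(smoothed, lm, tol_um = 5)
  partition <- partition_segments(smoothed, landmarks)
  list(nr = nr, nc = nc, centre = ctr, dense_outline = dense,
       trace = trace, smoothed = smoothed, landmarks = landmarks,
       partition = partition)
}

# band membership by radial depth: the outline is star-shaped about the
# frame centre (radius function of polar angle), so the annular band is the
# set of points whose radial distance from the outline, along their own
# ray, is at most band_width
in_band_radial <- function(spec, centre, x, y) {
  dx <- x - centre[1]; dy <- y - centre[2]
  rho <- sqrt(dx^2 + dy^2)
  r_out <- outline_radius(spec, atan2(dy, dx))
  rho <= r_out & rho >= r_out - spec$band_width
}

# metric stretch factor that produces a given measured circularity for the
# band cells of this generator. Calibrated once on reference simulations
# of the generator + morphometrics pipeline (window-3 smoothed pixel-edge
# boundaries); monotone interpolation between calibration knots.
stretch_for_circularity <- function(circ) {
  knots_lam <- c(2.50, 2.35, 2.20, 2.05, 1.90, 1.75, 1.60, 1.45, 1.30,
                 1.15, 1.00)
  knots_circ <- c(0.512, 0.527, 0.541, 0.561, 0.583, 0.606, 0.647, 0.683,
                  0.720, 0.751, 0.762)
  stats::approx(knots_circ, knots_lam,
                xout = pmin(pmax(circ, min(knots_circ)), max(knots_circ)),
                rule = 2)$y
}

#' Generate a synthetic epithelium with ground truth
#'
#' Seeds are placed in the annular band between the outline and its inward
#' offset with density matching the per-segment target areas, relaxed by
#' Lloyd iterations, then grown into an anisotropic power-diagram partition
#' of the band: each seed carries an area-preserving metric stretched along
#' an axis drawn from its segment's axial orientation distribution
#' (relative to the local outline normal), and per-seed power weights are
#' adapted so cell areas track their targets. Transition states are
#' injected by contracting randomly chosen interior junction edges to a
#' point (a radial remap of the disc spanned by the edge), verified against
#' the detector, until the target rate is met.
#'
#' @param spec a `synthetic_spec`.
#' @param seed integer RNG seed; the run is fully deterministic given
#'   (spec, seed).
#' @return list with `labels` (a label `pixel_grid`), `mesh` (a
#'   `cell_mesh`), `outline` (a `traced_outline`), `landmarks` (data.frame
#'   `name,x_um,y_um` for lm1-lm4), `partition`, `smoothed`, and `truth`
#'   (ground-truth manifest: per-cell region/axis/target area, transition
#'   states, landmark positions, seed, spec hash).
#' @export
generate_tissue <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(seed, function() generate_tissue_impl(spec, seed))
}

generate_tissue_impl <- function(spec, seed) {
  fr <- synthetic_frame(spec)
  px <- spec$pixel_size
  nr <- fr$nr; nc <- fr$nc

  # --- band mask on a coarse relaxation grid ------------------------------
  cpx <- max(1, 5 * px)
  cnr <- ceiling(nr * px / cpx); cnc <- ceiling(nc * px / cpx)
  ccol <- rep(seq_len(cnc), each = cnr)
  crow <- rep(seq_len(cnr), cnc)
  cxy <- cbind((ccol - 0.5) * cpx, (cnr - crow + 0.5) * cpx)
  in_band <- in_band_radial(spec, fr$centre, cxy[, 1], cxy[, 2])
  bxy <- cxy[in_band, , drop = FALSE]
  bseg <- segment_of_points(fr$partition, bxy)

  # --- seed placement by segment density ----------------------------------
  seg <- spec$segments
  seeds <- NULL; seed_seg <- character(0)
  for (k in seq_len(nrow(seg))) {
    pool <- which(bseg == seg$name[k])
    a_band <- length(pool) * cpx^2
    nk <- max(1L, round(a_band / seg$area_mean[k]))
    if (length(pool) < nk) stopf("infeasible packing in segment %s", seg$name[k])
    pick <- sample(pool, nk)
    pts <- bxy[pick, , drop = FALSE] +
      matrix(stats::runif(2 * nk, -cpx / 2, cpx / 2), ncol = 2)
    seeds <- rbind(seeds, pts)
    seed_seg <- c(seed_seg, rep(seg$name[k], nk))
  }
  ns <- nrow(seeds)

  # --- isotropic Lloyd relaxation on the coarse band ----------------------
  for (it in 1:6) {
    lab <- nearest_seed(bxy, seeds)
    seeds <- rowsum(bxy, lab) / as.vector(table(lab))
    # a seed can lose all pixels; re-drop it onto a random band pixel
    missing <- setdiff(seq_len(ns), sort(unique(lab)))
    if (length(missing)) {
      seeds <- rbind(seeds, bxy[sample(nrow(bxy), length(missing)), ,
                                drop = FALSE])
    }
    if (nrow(seeds) != ns) seeds <- seeds[seq_len(ns), , drop = FALSE]
  }
  # refresh segment of each relaxed seed
  seed_seg <- segment_of_points(fr$partition, seeds)
  seed_seg[is.na(seed_seg)] <- seg$name[1]
  si <- match(seed_seg, seg$name)

  # --- per-seed orientation, stretch and area targets ---------------------
  near <- nearest_seed(seeds, fr$smoothed$samples) # nearest outline sample
  m <- nrow(fr$smoothed$samples)
  tang <- fr$smoothed$samples[ifelse(near == m, 1, near + 1), , drop = FALSE] -
    fr$smoothed$samples[ifelse(near == 1, m, near - 1), , drop = FALSE]
  # axial angle of the local outline normal (sign irrelevant on the axial
  # scale): normal = tangent rotated 90 degrees
  nrm_ang <- fold_axis180(rad2deg(atan2(tang[, 1], -tang[, 2])))
  theta <- fold_axis180(nrm_ang + seg$orientation_mean_deg[si] +
                          stats::rnorm(ns, 0, seg$orientation_sd_deg[si]))
  lam <- stretch_for_circularity(seg$circularity[si])
  a_target <- pmax(25, stats::rnorm(ns, seg$area_mean[si], seg$area_sd[si]))

  # --- anisotropic power-weight adaptation on the coarse band -------------
  w <- numeric(ns)
  for (it in 1:6) {
    lab <- nearest_seed_metric(bxy, seeds, theta, lam, w)
    area <- numeric(ns)
    tb <- table(lab)
    area[as.integer(names(tb))] <- as.numeric(tb) * cpx^2
    w <- w + 0.7 * (a_target - area)
  }

  # --- final assignment on the fine grid ----------------------------------
  labels <- assign_labels_fine(spec, fr, seeds, theta, lam, w)
  labels <- fix_label_components(labels)
  labels <- merge_tiny_cells(labels, min_px = floor(25 / px^2 / 4))
  labels <- fix_label_components(labels)
  labels <- merge_tiny_cells(labels, min_px = floor(25 / px^2 / 4))
  labels <- fix_label_components(labels)

  # --- transition-state injection -----------------------------------------
  keep_ids <- sort(unique(as.vector(labels))); keep_ids <- keep_ids[keep_ids > 0]
  n_cells <- length(keep_ids)
  n_target <- round(spec$ts_rate_per_100 * n_cells / 100)
  inj <- inject_transition_states(labels, px, n_target, spec$ts_order)
  labels <- inj$labels

  grid <- pixel_grid(labels, px, "labels")
  mesh <- mesh_from_labels(grid)
  mesh <- assign_cell_regions(mesh, fr$partition)

  ids <- cell_ids(mesh)
  truth_cells <- data.frame(
    cell_id = ids,
    region = vapply(mesh$cells, function(cl) cl$region, character(1)),
    true_orientation_deg = theta[match(ids, seq_len(ns))],
    target_area_um2 = a_target[match(ids, seq_len(ns))],
    segment_area_mean = seg$area_mean[si][match(ids, seq_len(ns))],
    segment_circularity = seg$circularity[si][match(ids, seq_len(ns))])
  ts_final <- detect_transition_states(mesh)
  truth <- list(cells = truth_cells,
                ts = ts_final[, c("ts_id", "x_um", "y_um", "order", "kind")],
                n_ts_requested = n_target,
                n_ts_injected = inj$n_injected,
                n_ts_incidental = inj$n_incidental,
                landmarks = fr$landmarks$points,
                seed = seed,
                spec_hash = spec_hash(spec))
  lm_df <- data.frame(name = paste0("lm", 1:4),
                      x_um = fr$landmarks$points[1:4, 1],
                      y_um = fr$landmarks$points[1:4, 2])
  list(labels = grid, mesh = mesh, outline = fr$trace, landmarks = lm_df,
       partition = fr$partition, smoothed = fr$smoothed, truth = truth)
}

# nearest (isotropic) seed index for each point
nearest_seed <- function(xy, seeds) {
  n <- nrow(xy)
  out <- integer(n)
  step <- 20000
  for (s in seq(1, n, by = step)) {
    e <- min(s + step - 1, n)
    d2 <- outer(xy[s:e, 1], seeds[, 1], "-")^2 +
      outer(xy[s:e, 2], seeds[, 2], "-")^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

# nearest seed under per-seed area-preserving anisotropic metric with power
# weights: d_i^2 = (u/lam_i)^2 + (lam_i v)^2 - w_i, (u, v) in the frame
# rotated to the seed's axis
nearest_seed_metric <- function(xy, seeds, theta_deg, lam, w) {
  n <- nrow(xy); ns <- nrow(seeds)
  ct <- cos(deg2rad(theta_deg)); st <- sin(deg2rad(theta_deg))
  out <- integer(n)
  step <- 20000
  for (s in seq(1, n, by = step)) {
    e <- min(s + step - 1, n)
    dx <- outer(xy[s:e, 1], seeds[, 1], "-")
    dy <- outer(xy[s:e, 2], seeds[, 2], "-")
    u <- sweep(dx, 2, ct, "*") + sweep(dy, 2, st, "*")
    v <- -sweep(dx, 2, st, "*") + sweep(dy, 2, ct, "*")
    d2 <- sweep(u, 2, lam, "/")^2 + sweep(v, 2, lam, "*")^2
    d2 <- sweep(d2, 2, w, "-")
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

# fine-grid assignment with per-seed windows and a safety pass
assign_labels_fine <- function(spec, fr, seeds, theta, lam, w) {
  px <- spec$pixel_size
  nr <- fr$nr; nc <- fr$nc
  best <- matrix(Inf, nr, nc)
  labm <- matrix(0L, nr, nc)
  ct <- cos(deg2rad(theta)); st <- sin(deg2rad(theta))
  rad <- lam * 1.8 * sqrt(max(spec$segments$area_mean) / pi) + 4  # window radius
  for (i in seq_len(nrow(seeds))) {
    c0 <- seeds[i, 1] / px + 0.5; r0 <- nr - seeds[i, 2] / px + 0.5
    rw <- ceiling(rad[i] / px)
    rows <- max(1, floor(r0 - rw)):min(nr, ceiling(r0 + rw))
    cols <- max(1, floor(c0 - rw)):min(nc, ceiling(c0 + rw))
    X <- (matrix(cols, length(rows), length(cols), byrow = TRUE) - 0.5) * px -
      seeds[i, 1]
    Y <- (nr - matrix(rows, length(rows), length(cols)) + 0.5) * px -
      seeds[i, 2]
    u <- ct[i] * X + st[i] * Y
    v <- -st[i] * X + ct[i] * Y
    d2 <- (u / lam[i])^2 + (v * lam[i])^2 - w[i]
    sub_best <- best[rows, cols]
    upd <- d2 < sub_best
    sub_lab <- labm[rows, cols]
    sub_lab[upd] <- i
    sub_best[upd] <- d2[upd]
    best[rows, cols] <- sub_best
    labm[rows, cols] <- sub_lab
  }
  # band mask on the fine grid (radial depth, star-shaped outline)
  fcol <- rep(seq_len(nc), each = nr)
  frow <- rep(seq_len(nr), nc)
  fx <- (fcol - 0.5) * px
  fy <- (nr - frow + 0.5) * px
  dmask <- matrix(in_band_radial(spec, fr$centre, fx, fy), nr, nc)
  labm[!dmask] <- 0L
  # safety pass for band pixels missed by every window
  miss <- which(dmask & labm == 0L)
  if (length(miss)) {
    my <- cbind(((miss - 1) %/% nr + 1 - 0.5) * px,
                (nr - ((miss - 1) %% nr + 1) + 0.5) * px)
    labm[miss] <- nearest_seed_metric(my, seeds, theta, lam, w)
  }
  labm
}

# connected-component repair: keep each label's largest 4-connected
# component, giving minor fragments to the most frequent neighbouring
# label. Reassignment can itself disconnect the receiving label, so the
# pass iterates globally; any fragment still multi-component after
# `max_pass` passes becomes a fresh label of its own (always valid).
fix_label_components <- function(labm, max_pass = 6L) {
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (lab in setdiff(sort(unique(as.vector(labm))), 0L)) {
      res <- split_minor_components(labm, lab)
      if (is.null(res)) next
      nb <- neighbour_labels(labm, res$idx)
      nb <- nb[nb != lab & nb > 0L]
      repl <- if (length(nb)) as.integer(names(sort(table(nb),
                                                    decreasing = TRUE))[1]) else 0L
      labm[res$idx] <- repl
      changed <- TRUE
    }
    if (!changed) return(labm)
  }
  # fallback: promote remaining minor fragments to new labels
  repeat {
    promoted <- FALSE
    for (lab in setdiff(sort(unique(as.vector(labm))), 0L)) {
      res <- split_minor_components(labm, lab)
      if (is.null(res)) next
      labm[res$idx] <- max(labm) + 1L
      promoted <- TRUE
    }
    if (!promoted) break
  }
  labm
}

# full-matrix indices of one minor component of `lab` (NULL if connected)
split_minor_components <- function(labm, lab) {
  nr <- nrow(labm)
  idx <- which(labm == lab)
  if (!length(idx)) return(NULL)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  rows <- min(r):max(r); cols <- min(cc):max(cc)
  sub <- labm[rows, cols, drop = FALSE]
  comp <- label_components(sub == lab)
  if (comp$n <= 1) return(NULL)
  keep <- which.max(comp$sizes)
  pick <- which(comp$comp != keep & !is.na(comp$comp) &
                  comp$comp == setdiff(seq_len(comp$n), keep)[1])
  sr <- ((pick - 1L) %% length(rows)) + 1L
  scx <- ((pick - 1L) %/% length(rows)) + 1L
  list(idx = (cols[scx] - 1L) * nr + rows[sr])
}

# 4-connected components of a logical matrix via vectorised BFS flood fill
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- integer(nr * nc)
  idx_all <- which(mask)
  ncomp <- 0L
  sizes <- integer(0)
  for (start in idx_all) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    comp[start] <- ncomp
    frontier <- start
    size <- 0L
    while (length(frontier)) {
      size <- size + length(frontier)
      r <- ((frontier - 1L) %% nr) + 1L
      nb <- c(frontier[r > 1L] - 1L,
              frontier[r < nr] + 1L,
              frontier[frontier > nr] - nr,
              frontier[frontier <= nr * (nc - 1L)] + nr)
      nb <- unique(nb)
      nb <- nb[mask[nb] & comp[nb] == 0L]
      comp[nb] <- ncomp
      frontier <- nb
    }
    sizes[ncomp] <- size
  }
  comp_m <- matrix(NA_integer_, nr, nc)
  comp_m[comp != 0L] <- comp[comp != 0L]
  list(comp = comp_m, n = ncomp, sizes = sizes)
}

neighbour_labels <- function(labm, idx) {
  nr <- nrow(labm); nc <- ncol(labm)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  c(labm[cbind(pmax(r - 1L, 1L), cc)], labm[cbind(pmin(r + 1L, nr), cc)],
    labm[cbind(r, pmax(cc - 1L, 1L))], labm[cbind(r, pmin(cc + 1L, nc))])
}

# absorb cells below min_px pixels into their largest neighbour
merge_tiny_cells <- function(labm, min_px) {
  tb <- table(labm[labm > 0L])
  small <- as.integer(names(tb))[tb < min_px]
  for (lab in small) {
    idx <- which(labm == lab)
    nb <- neighbour_labels(labm, idx)
    nb <- nb[nb != lab & nb > 0L]
    if (!length(nb)) { labm[idx] <- 0L; next }
    labm[idx] <- as.integer(names(sort(table(nb), decreasing = TRUE))[1])
  }
  labm
}
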