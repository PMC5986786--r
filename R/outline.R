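# The local anatomical model: a manually traced ventricular circumference is
# smoothed with a closed composite cubic Bezier (Catmull-Rom construction),
# the cardiac centre is the centroid of the smoothed circumference samples,
# four given surface landmarks plus two computed outer-curvature points
# partition the ventricle into six named segments about the centroid.

SEGMENT_NAMES <- c("IC", "OFT", "OC_near_OFT", "OC_middle", "OC_near_AV", "AV")

#' Construct a traced outline
#'
#' @param points n x 2 matrix of ordered outline points (um), closed
#'   implicitly (first point not repeated); n >= 8. Consecutive duplicate
#'   points are dropped with a warning.
#' @return a `traced_outline`.
#' @export
traced_outline <- function(points) {
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  n0 <- nrow(p)
  if (n0 > 1 && all(p[1, ] == p[n0, ])) p <- p[-n0, , drop = FALSE]
  dup <- rowSums((p - rbind(p[nrow(p), ], p[-nrow(p), , drop = FALSE]))^2) == 0
  if (any(dup)) {
    warnf("dropped %d duplicate trace point(s)", sum(dup))
    p <- p[!dup, , drop = FALSE]
  }
  if (nrow(p) < 8) stopf("traced outline needs >= 8 distinct points")
  if (poly_self_intersects(p)) stopf("traced outline is self-intersecting")
  structure(list(points = p), class = "traced_outline")
}

#' Smooth a traced outline with a closed composite cubic Bezier
#'
#' Each span between consecutive trace points becomes a cubic Bezier whose
#' control points are derived from the neighbouring-point chords
#' (Catmull-Rom construction, tension 0.5), giving a C1 closed interpolating
#' curve with no free parameters beyond the sampling density. The cardiac
#' centre is the arithmetic mean of the curve samples.
#'
#' @param traced a `traced_outline` (or n x 2 matrix).
#' @param samples_per_span samples per Bezier span (uniform in parameter).
#' @return a `smoothed_outline`: `samples` (m x 2, um, counter-clockwise),
#'   `arc` (cumulative arc length starting at 0), `total_arc`, `centroid`.
#' @export
smooth_outline <- function(traced, samples_per_span = 20) {
  if (!inherits(traced, "traced_outline")) traced <- traced_outline(traced)
  p <- traced$points
  # orient counter-clockwise so arc length increases CCW
  if (poly_signed_area(p) < 0) p <- p[nrow(p):1, , drop = FALSE]
  n <- nrow(p)
  t <- seq(0, 1, length.out = samples_per_span + 1)[-(samples_per_span + 1)]
  b0 <- (1 - t)^3; b1 <- 3 * t * (1 - t)^2; b2 <- 3 * t^2 * (1 - t); b3 <- t^3
  idx <- function(i) ((i - 1) %% n) + 1
  samples <- matrix(0, n * samples_per_span, 2)
  for (i in seq_len(n)) {
    p0 <- p[idx(i), ]; p1 <- p[idx(i + 1), ]
    pm <- p[idx(i - 1), ]; pp <- p[idx(i + 2), ]
    c1 <- p0 + (p1 - pm) / 6
    c2 <- p1 - (pp - p0) / 6
    rows <- ((i - 1) * samples_per_span + 1):(i * samples_per_span)
    samples[rows, 1] <- b0 * p0[1] + b1 * c1[1] + b2 * c2[1] + b3 * p1[1]
    samples[rows, 2] <- b0 * p0[2] + b1 * c1[2] + b2 * c2[2] + b3 * p1[2]
  }
  seg <- sqrt(rowSums((rbind(samples[-1, , drop = FALSE], samples[1, ]) -
                         samples)^2))
  if (any(seg == 0)) stopf("degenerate outline: zero-length curve segment")
  arc <- c(0, cumsum(seg[-length(seg)]))
  structure(list(samples = samples, arc = arc, total_arc = sum(seg),
                 centroid = colMeans(samples),
                 samples_per_span = samples_per_span),
            class = "smoothed_outline")
}

#' @export
print.smoothed_outline <- function(x, ...) {
  cat(sprintf("<smoothed_outline: %d samples, arc %.1f um, centroid (%.1f, %.1f)>\n",
              nrow(x$samples), x$total_arc, x$centroid[1], x$centroid[2]))
  invisible(x)
}

# interpolated point at arc position s (wrapped)
outline_point_at_arc <- function(smoothed, s) {
  L <- smoothed$total_arc
  s <- s %% L
  arc <- smoothed$arc
  i <- findInterval(s, arc)
  p0 <- smoothed$samples[i, ]
  p1 <- smoothed$samples[if (i == nrow(smoothed$samples)) 1 else i + 1, ]
  s0 <- arc[i]
  seg <- if (i == nrow(smoothed$samples)) L - s0 else arc[i + 1] - s0
  w <- if (seg > 0) (s - s0) / seg else 0
  p0 + w * (p1 - p0)
}

#' Place the six anatomical landmarks on a smoothed outline
#'
#' The four given landmarks (1: AV joins IC, 2: IC joins OFT, 3: OFT joins
#' OC, 4: OC joins AV) are snapped to the nearest outline sample. Two
#' additional points are computed at one-third (5) and two-thirds (6) of the
#' outer-curvature arc from landmark 3 to landmark 4, travelling
#' counter-clockwise (set `outer_ccw = FALSE` for mirrored hearts).
#'
#' @param smoothed a `smoothed_outline`.
#' @param lm 4 x 2 matrix of landmark coordinates (rows lm1..lm4, um), or a
#'   data.frame with columns `name` (`lm1`..`lm4`), `x_um`, `y_um`.
#' @param tol_um maximum allowed distance from a given landmark to the
#'   outline (default 5 um).
#' @param outer_ccw direction of the outer curvature from landmark 3 to 4.
#' @return a `landmark_set`: `points` (6 x 2 matrix, rows `lm1`..`lm6`),
#'   `arc` (arc positions), `outer_ccw`.
#' @export
place_landmarks <- function(smoothed, lm, tol_um = 5, outer_ccw = TRUE) {
  stopifnot(inherits(smoothed, "smoothed_outline"))
  lm <- landmark_matrix(lm)
  pts <- matrix(NA_real_, 6, 2,
                dimnames = list(paste0("lm", 1:6), c("x", "y")))
  arcs <- numeric(6)
  for (i in 1:4) {
    d2 <- (smoothed$samples[, 1] - lm[i, 1])^2 +
      (smoothed$samples[, 2] - lm[i, 2])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > tol_um)
      stopf("landmark lm%d is %.2f um from the outline (tolerance %g um)",
            i, sqrt(d2[j]), tol_um)
    pts[i, ] <- smoothed$samples[j, ]
    arcs[i] <- smoothed$arc[j]
  }
  # landmarks must appear in CCW order 1, 2, 3, 4 around the outline
  rel <- (arcs[2:4] - arcs[1]) %% smoothed$total_arc
  if (any(diff(c(0, rel)) <= 0))
    stopf("landmarks are not in counter-clockwise order 1,2,3,4")
  L <- smoothed$total_arc
  D <- if (outer_ccw) (arcs[4] - arcs[3]) %% L else -((arcs[3] - arcs[4]) %% L)
  arcs[5] <- (arcs[3] + D / 3) %% L
  arcs[6] <- (arcs[3] + 2 * D / 3) %% L
  pts[5, ] <- outline_point_at_arc(smoothed, arcs[5])
  pts[6, ] <- outline_point_at_arc(smoothed, arcs[6])
  structure(list(points = pts, arc = arcs, outer_ccw = outer_ccw),
            class = "landmark_set")
}

landmark_matrix <- function(lm) {
  if (is.data.frame(lm)) {
    need <- paste0("lm", 1:4)
    if (!all(need %in% lm$name))
      stopf("expected 4 landmarks named %s; missing: %s",
            paste(need, collapse = ", "),
            paste(setdiff(need, lm$name), collapse = ", "))
    lm <- as.matrix(lm[match(need, lm$name), c("x_um", "y_um")])
  }
  lm <- as.matrix(lm)
  if (nrow(lm) != 4 || ncol(lm) != 2)
    stopf("expected 4 landmarks (4 x 2), got %d x %d", nrow(lm), ncol(lm))
  storage.mode(lm) <- "double"
  lm
}

#' Partition the ventricle into six named segments
#'
#' Each segment is an angular sector about the outline centroid, bounded by
#' rays through consecutive landmarks in the counter-clockwise scheme:
#' 1-2 IC, 2-3 OFT, 3-5 OC_near_OFT, 5-6 OC_middle, 6-4 OC_near_AV, 4-1 AV.
#'
#' @param smoothed a `smoothed_outline`.
#' @param landmarks a `landmark_set`.
#' @return a `segment_partition`: `centroid`, `segments` (data.frame of
#'   `name`, `from_deg`, `to_deg`, CCW polar intervals), `landmarks`.
#' @export
partition_segments <- function(smoothed, landmarks) {
  stopifnot(inherits(smoothed, "smoothed_outline"),
            inherits(landmarks, "landmark_set"))
  ctr <- smoothed$centroid
  seq_lm <- c(1, 2, 3, 5, 6, 4)
  ang <- sapply(seq_lm, function(i) {
    v <- landmarks$points[i, ] - ctr
    rad2deg(atan2(v[2], v[1])) %% 360
  })
  if (anyDuplicated(round(ang, 9)))
    stopf("two landmarks lie at the same polar angle about the centroid")
  widths <- diff(c(ang, ang[1] + 360)) %% 360
  if (abs(sum(widths) - 360) > 1e-6)
    stopf("landmark rays are not in counter-clockwise order; sectors would overlap")
  segs <- data.frame(name = SEGMENT_NAMES,
                     from_deg = ang,
                     to_deg = (ang + widths) %% 360,
                     width_deg = widths)
  structure(list(centroid = ctr, segments = segs, landmarks = landmarks),
            class = "segment_partition")
}

#' @export
print.segment_partition <- function(x, ...) {
  cat("Six-segment partition about centroid (",
      sprintf("%.1f, %.1f", x$centroid[1], x$centroid[2]), "):\n", sep = "")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Which segment contains each point
#'
#' @param partition a `segment_partition`.
#' @param xy n x 2 matrix of points (um).
#' @return character vector of segment names; `NA` for a point coincident
#'   with the centroid.
#' @export
segment_of_points <- function(partition, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  v <- sweep(xy, 2, partition$centroid)
  ang <- rad2deg(atan2(v[, 2], v[, 1])) %% 360
  degenerate <- rowSums(v^2) == 0
  segs <- partition$segments
  # one shared reference angle and cumulative breaks give a genuine
  # partition: every angle falls in exactly one half-open sector
  rel <- (ang - segs$from_deg[1]) %% 360
  breaks <- cumsum(segs$width_deg)
  k <- findInterval(rel, c(0, breaks[-length(breaks)]))
  k[k < 1] <- 1
  k[rel >= breaks[length(breaks)]] <- 1   # numeric spill past 360 wraps
  out <- segs$name[k]
  out[degenerate] <- NA_character_
  if (any(degenerate)) warnf("%d point(s) coincide with the centroid; unassignable",
                             sum(degenerate))
  out
}

#' Assign region labels to the cells of a mesh
#'
#' Region = segment containing the cell centroid.
#'
#' @param mesh a `cell_mesh`.
#' @param partition a `segment_partition`.
#' @return the mesh with `region` set on every cell.
#' @export
assign_cell_regions <- function(mesh, partition) {
  ctr <- cell_centroids(mesh)
  reg <- segment_of_points(partition, ctr)
  for (i in seq_along(mesh$cells)) mesh$cells[[i]]$region <- reg[i]
  mesh
}

#' Axial angle of a cell axis against the local outline normal
#'
#' For each cell, the tangent of the smoothed outline at the sample nearest
#' the cell centroid is estimated by central difference; the outward normal
#' is the tangent rotated 90 degrees away from the cardiac centre. Under the
#' default "normal" convention the reported angle is
#' `fold(psi - normal_angle)` on the (-90, 90] axial scale, so a cell
#' elongated along the outward normal scores 0 and a circumferential cell
#' scores 90. The "tangent" convention reports `fold(psi - tangent_angle)`
#' instead.
#'
#' @param cell_axis_deg axial orientation(s) psi of the cell(s), degrees
#'   ([0, 180) scale, y-up); `NA` propagates.
#' @param smoothed a `smoothed_outline`.
#' @param cell_centroid n x 2 matrix (or length-2 vector) of centroids (um).
#' @param convention "normal" (default) or "tangent".
#' @return numeric vector of axial angles in (-90, 90].
#' @export
axial_angle <- function(cell_axis_deg, smoothed, cell_centroid,
                        convention = c("normal", "tangent")) {
  convention <- match.arg(convention)
  stopifnot(inherits(smoothed, "smoothed_outline"))
  xy <- matrix(as.numeric(cell_centroid), ncol = 2)
  stopifnot(length(cell_axis_deg) == nrow(xy))
  m <- nrow(smoothed$samples)
  out <- rep(NA_real_, length(cell_axis_deg))
  for (i in seq_along(cell_axis_deg)) {
    if (is.na(cell_axis_deg[i])) next
    d2 <- (smoothed$samples[, 1] - xy[i, 1])^2 +
      (smoothed$samples[, 2] - xy[i, 2])^2
    j <- which.min(d2)
    jp <- if (j == m) 1 else j + 1
    jm <- if (j == 1) m else j - 1
    tang <- smoothed$samples[jp, ] - smoothed$samples[jm, ]
    nrm <- c(-tang[2], tang[1])
    if (sum(nrm * (smoothed$samples[j, ] - smoothed$centroid)) < 0) nrm <- -nrm
    ref <- if (convention == "normal") nrm else tang
    ref_deg <- rad2deg(atan2(ref[2], ref[1]))
    out[i] <- fold_axial(cell_axis_deg[i] - ref_deg)
  }
  out
}

#' Per-cell axial angle table for a measured mesh
#'
#' Convenience wrapper joining [measure_cells()] orientations with
#' [axial_angle()]; cells with undefined axis (elongation 0) get `NA` with a
#' logged count.
#'
#' @param mesh a `cell_mesh` with regions assigned.
#' @param smoothed a `smoothed_outline`.
#' @param shapes optional precomputed [measure_cells()] table.
#' @param convention angle convention, see [axial_angle()].
#' @return data.frame `cell_id`, `region`, `angle_deg`, `convention`.
#' @export
cell_axial_angles <- function(mesh, smoothed, shapes = NULL,
                              convention = c("normal", "tangent")) {
  convention <- match.arg(convention)
  if (is.null(shapes)) shapes <- measure_cells(mesh)
  ctr <- cell_centroids(mesh)
  n_und <- sum(is.na(shapes$orientation_deg))
  if (n_und > 0)
    message(sprintf("%d cell(s) with undefined axis excluded from statistics",
                    n_und))
  ang <- axial_angle(shapes$orientation_deg, smoothed, ctr, convention)
  data.frame(cell_id = shapes$cell_id,
             region = vapply(mesh$cells, function(cl)
               cl$region %||% NA_character_, character(1)),
             angle_deg = ang,
             convention = convention)
}

#' Cardiac looping angle
#'
#' Acute angle in [0, 90] degrees between the line through the two
#' atrio-ventricular-junction endpoints and the embryo midline axis;
#' invariant to swapping the endpoints and to the midline sign.
#'
#' @param avj_p1,avj_p2 AVJ endpoints (length-2, um).
#' @param midline_vec midline direction vector (length-2, any nonzero
#'   magnitude).
#' @return angle in degrees.
#' @export
looping_angle <- function(avj_p1, avj_p2, midline_vec) {
  u <- as.numeric(avj_p2) - as.numeric(avj_p1)
  v <- as.numeric(midline_vec)
  if (sum(u^2) == 0) stopf("AVJ endpoints coincide")
  if (sum(v^2) == 0) stopf("midline vector has zero length")
  ct <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  rad2deg(acos(pmin(1, ct)))
}

#' Tabulate looped versus unlooped explants
#'
#' Count-to-rounded-percent arithmetic for explant culture outcomes
#' (percent rounded half-up to integer).
#'
#' @param n_unlooped,n_total integer counts.
#' @return list with `n_unlooped`, `n_total`, `percent_unlooped`.
#' @export
looping_tabulation <- function(n_unlooped, n_total) {
  if (n_total <= 0 || n_unlooped < 0 || n_unlooped > n_total)
    stopf("invalid explant counts")
  list(n_unlooped = n_unlooped, n_total = n_total,
       percent_unlooped = round_half_up(100 * n_unlooped / n_total))
}
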