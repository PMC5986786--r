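# Shared numeric and polygon helpers. Polygons are n x 2 matrices of (x, y)
# in micrometres, open representation (first vertex not repeated), CCW for
# positive area in the y-up mathematical frame used throughout the package.

#' Round half away from zero
#'
#' Deterministic "school" rounding used for reported percentages, where
#' `base::round()` would round half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Fold an angle onto the axial (-90, 90] scale
#'
#' Axial angles are defined modulo 180 degrees; the half-open interval with
#' ties at -90 mapped to +90 gives a deterministic representative.
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles in (-90, 90].
#' @export
fold_axial <- function(deg) {
  y <- deg %% 180
  ifelse(y > 90, y - 180, y)
}

#' Fold an angle onto the [0, 180) axial scale
#' @param deg numeric vector of angles in degrees.
#' @return angles in [0, 180).
#' @export
fold_axis180 <- function(deg) deg %% 180

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

as_poly <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2) stop("polygon must be an n x 2 matrix")
  # drop an explicitly repeated closing vertex
  n <- nrow(p)
  if (n > 1 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3) stop("polygon needs at least 3 distinct vertices")
  p
}

poly_signed_area <- function(p) {
  p <- as_poly(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_perimeter <- function(p) {
  p <- as_poly(p)
  d <- p[c(2:nrow(p), 1), ] - p
  sum(sqrt(rowSums(d^2)))
}

poly_centroid <- function(p) {
  p <- as_poly(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Exact area-weighted second central moment (covariance) tensor of a polygon,
# by Green's-theorem closed forms; independent of vertex spacing.
poly_covariance <- function(p) {
  p <- as_poly(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (a < 0) { # ensure CCW so the moment formulas carry positive weight
    p <- p[nrow(p):1, , drop = FALSE]
    return(poly_covariance(p))
  }
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum(cr * (y^2 + y * yn + yn^2)) / 12      # integral of y^2
  iyy <- sum(cr * (x^2 + x * xn + xn^2)) / 12      # integral of x^2
  ixy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  m <- matrix(c(iyy - a * cx^2, ixy - a * cx * cy,
                ixy - a * cx * cy, ixx - a * cy^2), 2, 2) / a
  list(area = a, centroid = c(cx, cy), cov = m)
}

# Vectorised ray-casting point-in-polygon (boundary points may fall either
# way; callers that care use tolerance-based tests).
points_in_poly <- function(px, py, poly) {
  poly <- as_poly(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

# Do segments (p1,p2) and (p3,p4) properly intersect?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# Simple O(n^2) self-intersection test for a closed polyline.
poly_self_intersects <- function(p) {
  p <- as_poly(p)
  n <- nrow(p)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):n) {
      # skip segments sharing a vertex
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (segments_intersect(p[idx[i, 1], ], p[idx[i, 2], ],
                             p[idx[j, 1], ], p[idx[j, 2], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Bilinear interpolation on a matrix at fractional (row, col) positions.
# Positions outside [1, nrow] x [1, ncol] return NA.
bilinear_sample <- function(mat, row, col) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- floor(row); c0 <- floor(col)
  r0 <- pmin(pmax(r0, 1), nr - 1)
  c0 <- pmin(pmax(c0, 1), nc - 1)
  fr <- row - r0; fc <- col - c0
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  v <- (1 - fr) * (1 - fc) * mat[cbind(r0, c0)] +
    (1 - fr) * fc * mat[cbind(r0, c0 + 1)] +
    fr * (1 - fc) * mat[cbind(r0 + 1, c0)] +
    fr * fc * mat[cbind(r0 + 1, c0 + 1)]
  v[!ok] <- NA_real_
  v
}

# Single-linkage clustering of 2-D points with distance threshold `tol`;
# returns an integer cluster id per point. Small sets use hclust; large
# sets a grid-bucket union-find with identical single-linkage semantics.
cluster_points <- function(xy, tol) {
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  if (n == 1 || tol <= 0) return(seq_len(n))
  if (n <= 2000) {
    hc <- stats::hclust(stats::dist(xy), method = "single")
    return(stats::cutree(hc, h = tol))
  }
  bx <- floor(xy[, 1] / tol); by <- floor(xy[, 2] / tol)
  keys <- paste(bx, by)
  env <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) {
    assign(keys[i], c(get0(keys[i], envir = env, ifnotfound = integer(0)), i),
           envir = env)
  }
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  t2 <- tol^2
  for (i in seq_len(n)) {
    for (dx in -1:1) {
      for (dy in -1:1) {
        k <- paste(bx[i] + dx, by[i] + dy)
        for (j in get0(k, envir = env, ifnotfound = integer(0))) {
          if (j <= i) next
          if ((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2 <= t2) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
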