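# Transition-state injection by edge contraction on the label raster.
#
# A junction edge between cells A and B runs between two 3-fold vertices
# v1 = {A,B,C} and v2 = {A,B,D}. Contracting it to its midpoint q is
# realised as a radial remap of the disc centred at q that spans the edge:
# every pixel inside the disc takes the label found just outside the disc
# along the same ray from q. The four boundary arcs (A, C, B, D) thereby
# become four cones meeting at q, i.e. a vertex of order 4 (higher orders
# arise from discs spanning chains of edges). Each injection is verified
# against the same 2x2-block vertex scan used by the detector and rolled
# back if it did not produce exactly the intended vertex.

# main driver: inject up to n_target transition states (beyond those already
# present); returns modified labels plus bookkeeping
inject_transition_states <- function(labm, px, n_target, order = 4L,
                                     max_rounds = 4L) {
  merge_tol <- px * sqrt(2)
  vs <- raster_vertices(labm, px, merge_tol)
  incidental <- sum(vs$order >= 4L)
  ts_pos <- vs$pos[vs$order >= 4L, , drop = FALSE]
  n_have <- incidental
  n_injected <- 0L
  if (n_target < n_have) {
    # too many incidental near-degenerate vertices: dissolve the excess
    ord_shuffle <- sample(nrow(ts_pos))
    for (i in ord_shuffle) {
      if (n_have <= n_target) break
      res <- dissolve_ts(labm, px, ts_pos[i, ], merge_tol)
      if (!is.null(res)) {
        labm <- res
        n_have <- n_have - 1L
      }
    }
    if (n_have > n_target)
      warnf("could not dissolve %d excess transition state(s)",
            n_have - n_target)
    vs <- raster_vertices(labm, px, merge_tol)
    incidental <- sum(vs$order >= 4L)
    ts_pos <- vs$pos[vs$order >= 4L, , drop = FALSE]
    n_have <- incidental
  }
  if (n_target <= n_have)
    return(list(labels = labm, n_injected = 0L, n_incidental = incidental))
  for (round in seq_len(max_rounds)) {
    vs <- raster_vertices(labm, px, merge_tol)
    cand <- if (order >= 5L) rosette_candidates(labm, vs, px, order)
            else contraction_candidates(labm, vs, px)
    if (nrow(cand) == 0) break
    cand <- cand[sample(nrow(cand)), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      if (n_have >= n_target) break
      q <- c(cand$qx[i], cand$qy[i])
      r <- cand$r[i]
      # keep clear of existing transition states
      if (nrow(ts_pos) > 0 &&
          min((ts_pos[, 1] - q[1])^2 + (ts_pos[, 2] - q[2])^2) <
            (3 * r)^2) next
      res <- try_contract_disc(labm, px, q, r, cand$cells[[i]], merge_tol,
                               korder = cand$order[i])
      if (!is.null(res)) {
        labm <- res
        ts_pos <- rbind(ts_pos, q)
        n_have <- n_have + 1L
        n_injected <- n_injected + 1L
      }
    }
    if (n_have >= n_target) break
  }
  if (n_have < n_target)
    warnf("injected %d of %d requested transition states (candidates exhausted)",
          n_have - incidental, n_target - incidental)
  list(labels = labm, n_injected = n_injected, n_incidental = incidental)
}

# clustered junction vertices of a label raster (positions um, orders,
# incident label sets)
raster_vertices <- function(labm, px, merge_tol) {
  sc <- scan_junction_corners(labm, px)
  vv <- merge_corner_vertices(sc, merge_tol)
  if (length(vv) == 0)
    return(list(pos = matrix(numeric(0), 0, 2), order = integer(0),
                incident = list()))
  list(pos = t(vapply(vv, `[[`, numeric(2), "position")),
       order = vapply(vv, `[[`, integer(1), "order"),
       incident = lapply(vv, `[[`, "incident_cells"))
}

# enumerate contractible junction edges: adjacent cell pairs (A, B) whose
# shared boundary ends in exactly two 3-fold vertices {A,B,C}, {A,B,D},
# C != D, with a workable edge length
contraction_candidates <- function(labm, vs, px, min_len = 5 * px,
                                   max_len = 40 * px) {
  three <- which(vs$order == 3L)
  if (length(three) < 2) return(empty_candidates())
  key <- vapply(vs$incident[three], function(s) paste(s, collapse = "_"),
                character(1))
  # pairs of 3-fold vertices sharing exactly two cells
  out <- list()
  pair_env <- new.env(hash = TRUE)
  for (ii in seq_along(three)) {
    s <- vs$incident[[three[ii]]]
    for (ab in utils::combn(s, 2, simplify = FALSE)) {
      k <- paste(ab, collapse = "_")
      assign(k, c(get0(k, envir = pair_env, ifnotfound = integer(0)),
                  three[ii]), envir = pair_env)
    }
  }
  for (k in ls(pair_env)) {
    vids <- get(k, envir = pair_env)
    if (length(vids) != 2) next
    ab <- as.integer(strsplit(k, "_")[[1]])
    s1 <- vs$incident[[vids[1]]]; s2 <- vs$incident[[vids[2]]]
    C <- setdiff(s1, ab); D <- setdiff(s2, ab)
    if (length(C) != 1 || length(D) != 1 || C == D) next
    p1 <- vs$pos[vids[1], ]; p2 <- vs$pos[vids[2], ]
    len <- sqrt(sum((p1 - p2)^2))
    if (len < min_len || len > max_len) next
    q <- (p1 + p2) / 2
    q <- round(q / px) * px               # snap to a pixel corner
    df <- data.frame(qx = q[1], qy = q[2], r = len / 2 + 3 * px,
                     order = 4L)
    df$cells <- list(c(ab[1], ab[2], C, D))
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) return(empty_candidates())
  do.call(rbind, out)
}

# rosette candidates: a 3-fold vertex v plus (order - 4) + 1 of its edge
# neighbours; contracting the edges incident at v pulls `order` cells onto
# one point. Only order 5 (one vertex, two short edges) is generated; the
# same disc-remap machinery verifies the outcome.
rosette_candidates <- function(labm, vs, px, korder = 5L,
                               max_len = 40 * px) {
  three <- which(vs$order == 3L)
  if (length(three) < 3) return(empty_candidates())
  out <- list()
  for (vi in three) {
    s <- vs$incident[[vi]]
    # edge neighbours: other 3-fold vertices sharing exactly two cells
    nbrs <- list()
    for (vj in three) {
      if (vj == vi) next
      shared <- intersect(s, vs$incident[[vj]])
      if (length(shared) == 2) {
        third <- setdiff(vs$incident[[vj]], shared)
        d <- sqrt(sum((vs$pos[vi, ] - vs$pos[vj, ])^2))
        if (d <= max_len / 2 && length(third) == 1)
          nbrs[[length(nbrs) + 1L]] <- list(vj = vj, third = third, d = d)
      }
    }
    if (length(nbrs) < 2) next
    # pick the two closest neighbours with distinct outer cells
    ord <- order(vapply(nbrs, `[[`, numeric(1), "d"))
    nbrs <- nbrs[ord]
    pick <- NULL
    for (a in seq_along(nbrs)) {
      for (b in seq_along(nbrs)) {
        if (b <= a) next
        if (nbrs[[a]]$third != nbrs[[b]]$third) { pick <- c(a, b); break }
      }
      if (!is.null(pick)) break
    }
    if (is.null(pick)) next
    cells <- sort(unique(c(s, nbrs[[pick[1]]]$third, nbrs[[pick[2]]]$third)))
    if (length(cells) != 5) next
    q <- round(vs$pos[vi, ] / px) * px
    r <- max(nbrs[[pick[1]]]$d, nbrs[[pick[2]]]$d) + 3 * px
    df <- data.frame(qx = q[1], qy = q[2], r = r, order = 5L)
    df$cells <- list(cells)
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) return(empty_candidates())
  do.call(rbind, out)
}

empty_candidates <- function() {
  df <- data.frame(qx = numeric(0), qy = numeric(0), r = numeric(0),
                   order = integer(0))
  df$cells <- list()
  df
}

# remove a (near-)degenerate transition state: assign the small disc around
# the vertex to the incident cell with the longest boundary arc, turning the
# order-4 contact back into separated 3-fold vertices. NULL on failure.
dissolve_ts <- function(labm, px, q, merge_tol) {
  nr <- nrow(labm); nc <- ncol(labm)
  r <- 2.5 * px
  r_out <- r + 1.2 * px
  phi <- seq(0, 2 * pi, length.out = 181)[-181]
  ring <- label_at(labm, px, q[1] + r_out * cos(phi), q[2] + r_out * sin(phi))
  if (any(ring == 0L)) return(NULL)
  # try receiving labels in decreasing boundary-arc order
  cand_labels <- as.integer(names(sort(table(ring), decreasing = TRUE)))
  rw <- ceiling((r + 2 * px) / px)
  c0 <- q[1] / px + 0.5; r0 <- nr - q[2] / px + 0.5
  rows <- max(1, floor(r0 - rw)):min(nr, ceiling(r0 + rw))
  cols <- max(1, floor(c0 - rw)):min(nc, ceiling(c0 + rw))
  X <- (matrix(cols, length(rows), length(cols), byrow = TRUE) - 0.5) * px - q[1]
  Y <- (nr - matrix(rows, length(rows), length(cols)) + 0.5) * px - q[2]
  inside <- X^2 + Y^2 <= r^2
  sub <- labm[rows, cols]
  if (any(sub[inside] == 0L)) return(NULL)
  pad <- 3L
  vrow <- max(1, min(rows) - pad):min(nr, max(rows) + pad)
  vcol <- max(1, min(cols) - pad):min(nc, max(cols) + pad)
  for (to_label in cand_labels) {
    affected <- sort(unique(c(sub[inside], to_label)))
    sub2 <- sub
    sub2[inside] <- to_label
    lab2 <- labm
    lab2[rows, cols] <- sub2
    loc <- lab2[vrow, vcol]
    vs <- raster_vertices(loc, px, merge_tol)
    if (length(vs$order) && any(vs$order >= 4L)) next
    ok <- TRUE
    for (lab in affected) {
      if (!is.null(split_minor_components(lab2, lab))) { ok <- FALSE; break }
    }
    if (ok) return(lab2)
  }
  NULL
}

# label at um coordinates (nearest pixel), 0 outside the raster
label_at <- function(labm, px, x, y) {
  nr <- nrow(labm); nc <- ncol(labm)
  cc <- pmin(pmax(ceiling(x / px), 1L), nc)
  r <- pmin(pmax(nr - floor(y / px), 1L), nr)
  labm[cbind(r, cc)]
}

# attempt the radial-remap contraction; NULL if preconditions or
# post-verification fail
try_contract_disc <- function(labm, px, q, r, abcd, merge_tol,
                              korder = 4L) {
  nr <- nrow(labm); nc <- ncol(labm)
  r_out <- r + 1.2 * px
  # boundary arcs: exactly `korder` cyclic runs, one per involved cell
  phi <- seq(0, 2 * pi, length.out = 361)[-361]
  ring <- label_at(labm, px, q[1] + r_out * cos(phi), q[2] + r_out * sin(phi))
  runs <- rle(ring)
  if (length(runs$values) > 1 &&
      runs$values[1] == runs$values[length(runs$values)]) {
    runs$values <- runs$values[-length(runs$values)]
  }
  if (length(runs$values) != korder) return(NULL)
  if (!setequal(runs$values, abcd) || any(runs$values == 0L)) return(NULL)
  # disc pixels, all of which must belong to the four cells
  rw <- ceiling((r + 2 * px) / px)
  c0 <- q[1] / px + 0.5; r0 <- nr - q[2] / px + 0.5
  rows <- max(1, floor(r0 - rw)):min(nr, ceiling(r0 + rw))
  cols <- max(1, floor(c0 - rw)):min(nc, ceiling(c0 + rw))
  X <- (matrix(cols, length(rows), length(cols), byrow = TRUE) - 0.5) * px - q[1]
  Y <- (nr - matrix(rows, length(rows), length(cols)) + 0.5) * px - q[2]
  inside <- X^2 + Y^2 <= r^2
  sub <- labm[rows, cols]
  if (!all(sub[inside] %in% abcd)) return(NULL)
  ang <- atan2(Y[inside], X[inside])
  newlab <- label_at(labm, px, q[1] + r_out * cos(ang), q[2] + r_out * sin(ang))
  if (any(newlab == 0L) || !all(newlab %in% abcd)) return(NULL)
  sub2 <- sub
  sub2[inside] <- newlab
  lab2 <- labm
  lab2[rows, cols] <- sub2
  # verify locally: exactly one vertex of order >= 4 near q, nothing else new
  pad <- 3L
  vrow <- max(1, min(rows) - pad):min(nr, max(rows) + pad)
  vcol <- max(1, min(cols) - pad):min(nc, max(cols) + pad)
  loc <- lab2[vrow, vcol]
  vs <- raster_vertices(loc, px, merge_tol)
  if (!length(vs$order)) return(NULL)
  # local frame offset: position within `loc` + offset of its lower-left
  offx <- (min(vcol) - 1) * px
  offy <- (nr - max(vrow)) * px
  pos <- cbind(vs$pos[, 1] + offx, vs$pos[, 2] + offy)
  big <- which(vs$order >= 4L)
  if (length(big) != 1) return(NULL)
  d <- sqrt(sum((pos[big, ] - q)^2))
  if (d > 2 * merge_tol + px) return(NULL)
  if (vs$order[big] != korder) return(NULL)
  # every involved cell must remain a single connected component
  for (lab in abcd) {
    if (!is.null(split_minor_components(lab2, lab))) return(NULL)
  }
  lab2
}
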