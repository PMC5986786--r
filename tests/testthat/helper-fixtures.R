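# Shared fixtures and independent oracles, all built in code.

# regular k-gon (circumradius r, centred at c, optional rotation)
regular_polygon <- function(k, r = 1, centre = c(0, 0), rot = 0) {
  th <- rot + 2 * pi * (0:(k - 1)) / k
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

rect_polygon <- function(w, h, centre = c(0, 0)) {
  cbind(centre[1] + c(-w, w, w, -w) / 2, centre[2] + c(-h, -h, h, h) / 2)
}

rotate_poly <- function(p, deg, centre = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(p, 2, centre) %*% t(R), 2, centre, "+")
}

# hexagonal lattice label raster: every interior junction is 3-fold
hex_lattice_labels <- function(n_rows = 4, n_cols = 5, s = 8) {
  # assign each pixel to the nearest hex centre (offset rows)
  w <- ceiling(n_cols * s * 1.8); h <- ceiling(n_rows * s * 1.6)
  centres <- NULL
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      centres <- rbind(centres,
                       c(j * s * 1.5 + (i %% 2) * s * 0.75, i * s * 1.3))
    }
  }
  lab <- matrix(0L, h, w)
  cx <- rep(seq_len(w), each = h); cy <- rep(h:1, w) # y-up row flip
  d2 <- matrix(Inf, h, w); out <- matrix(0L, h, w)
  for (k in seq_len(nrow(centres))) {
    dd <- matrix((cx - centres[k, 1])^2 + (cy - centres[k, 2])^2, h, w)
    upd <- dd < d2
    out[upd] <- k; d2[upd] <- dd[upd]
  }
  out
}

# random Voronoi-style label raster (nearest of n seeds on an nr x nc
# grid). Discrete nearest-seed assignment can disconnect a label when
# seeds interleave; such fragments are repaired so every label is a valid
# 4-connected cell.
voronoi_labels <- function(n_seeds, nr, nc, seed = 1) {
  set.seed(seed)
  sx <- runif(n_seeds, 1, nc); sy <- runif(n_seeds, 1, nr)
  cx <- rep(seq_len(nc), each = nr); cy <- rep(nr:1, nc)
  d2 <- rep(Inf, nr * nc); out <- integer(nr * nc)
  for (k in seq_len(n_seeds)) {
    dd <- (cx - sx[k])^2 + (cy - (nr - sy[k] + 1))^2
    upd <- dd < d2
    out[upd] <- k; d2[upd] <- dd[upd]
  }
  cardiomorph:::fix_label_components(matrix(out, nr, nc))
}

# independent oracle: exhaustive scan of every 2x2 pixel block for corners
# where >= 3 distinct nonzero labels meet; plain double loop, no reuse of
# package internals
oracle_junctions <- function(labels, pixel_size) {
  nr <- nrow(labels); nc <- ncol(labels)
  res <- list()
  for (r in 1:(nr - 1)) {
    for (cc in 1:(nc - 1)) {
      block <- c(labels[r, cc], labels[r, cc + 1],
                 labels[r + 1, cc], labels[r + 1, cc + 1])
      u <- unique(block[block > 0])
      if (length(u) >= 3) {
        res[[length(res) + 1]] <- list(
          x = cc * pixel_size, y = (nr - r) * pixel_size,
          labels = sort(u))
      }
    }
  }
  res
}

# oracle clustering identical to the spec'd rule: single linkage at tol,
# union of incident sets, mean position (independent implementation)
oracle_cluster <- function(raw, tol) {
  if (length(raw) == 0) return(list())
  xy <- do.call(rbind, lapply(raw, function(v) c(v$x, v$y)))
  n <- nrow(xy)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (grp[i] != grp[j] &&
            sqrt(sum((xy[i, ] - xy[j, ])^2)) <= tol) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed || n == 1) break
  }
  lapply(split(seq_len(n), grp), function(ii) {
    list(pos = colMeans(xy[ii, , drop = FALSE]),
         labels = sort(unique(unlist(lapply(raw[ii], `[[`, "labels")))))
  })
}

# cache of generated tissues shared across test files
.tissue_cache <- new.env(parent = emptyenv())
cached_tissue <- function(seed, spec = synthetic_spec()) {
  key <- paste0(cardiomorph:::spec_hash(spec), "_", seed)
  if (!exists(key, envir = .tissue_cache))
    assign(key, generate_tissue(spec, seed = seed), envir = .tissue_cache)
  get(key, envir = .tissue_cache)
}

# circle trace fixture
circle_trace <- function(n = 24, r = 50, centre = c(60, 60)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)

# generator configuration for the outflow-tract orientation-recovery
# experiment (OFT-dominant ring, ~86 OFT cells, mean 90 deg, s.d. 15 deg)
oft_recovery_spec <- function() preset_spec("oft90")
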