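test_that("a 2x2 raster of four labels yields one interior 4-fold vertex", {
  m <- matrix(as.integer(c(1, 3, 2, 4)), 2, 2)
  mesh <- mesh_from_labels(m, merge_tol_um = 0, pixel_size = 1)
  expect_length(mesh$cells, 4)
  expect_length(mesh$vertices, 1)
  expect_equal(mesh$vertices[[1]]$order, 4L)
  expect_equal(mesh$vertices[[1]]$position, c(1, 1))
  expect_setequal(mesh$vertices[[1]]$incident_cells, 1:4)
})

test_that("hexagonal lattice has only 3-fold interior vertices", {
  lab <- hex_lattice_labels()
  mesh <- mesh_from_labels(lab, pixel_size = 1)
  ords <- vapply(mesh$vertices, `[[`, integer(1), "order")
  expect_true(all(ords == 3L))
  expect_equal(nrow(detect_transition_states(mesh)), 0)
})

test_that("vertex detection equals the exhaustive 2x2-block oracle on Voronoi rasters", {
  for (seed in 1:3) {
    lab <- voronoi_labels(50, 60, 64, seed = seed)
    tol <- sqrt(2)
    mesh <- mesh_from_labels(lab, merge_tol_um = tol, pixel_size = 1)
    oracle <- oracle_cluster(oracle_junctions(lab, 1), tol)
    expect_equal(length(mesh$vertices), length(oracle))
    mp <- t(vapply(mesh$vertices, `[[`, numeric(2), "position"))
    op <- t(vapply(oracle, `[[`, numeric(2), "pos"))
    om <- op[order(op[, 1], op[, 2]), , drop = FALSE]
    oracle <- oracle[order(op[, 1], op[, 2])]
    expect_equal(unname(mp), unname(om), tolerance = 1e-12)
    for (i in seq_along(oracle)) {
      expect_equal(mesh$vertices[[i]]$incident_cells,
                   oracle[[i]]$labels)
    }
  }
})

test_that("cell areas from pixel-edge boundaries conserve the raster area exactly", {
  lab <- voronoi_labels(20, 40, 40, seed = 7)
  lab[lab == 3L] <- 0L  # punch a background hole
  mesh <- mesh_from_labels(lab, pixel_size = 0.5)
  areas <- vapply(mesh$cells, cell_area, numeric(1))
  expect_equal(sum(areas), sum(lab > 0) * 0.25, tolerance = 1e-12)
  expect_equal(mesh$tissue_area_um2, sum(lab > 0) * 0.25)
})

test_that("a label with disconnected components is rejected by name", {
  m <- matrix(as.integer(c(1, 2, 1, 2, 2, 2, 1, 2, 1)), 3, 3)
  expect_error(mesh_from_labels(m, pixel_size = 1), "label 1")
})

test_that("mesh serialisation is deterministic and round-trips", {
  tis <- cached_tissue(1)
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_mesh_geojson(tis$mesh, f1)
  write_mesh_geojson(tis$mesh, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_mesh_geojson(f1, snap_tol_um = 1e-9)
  expect_equal(length(back$cells), length(tis$mesh$cells))
  # topology: same adjacency pairs
  key <- function(m) paste(m$adjacency$cell_a, m$adjacency$cell_b)
  expect_setequal(key(back), key(tis$mesh))
  # coordinates within 1e-9 um
  b1 <- do.call(rbind, lapply(tis$mesh$cells, `[[`, "boundary"))
  b2 <- do.call(rbind, lapply(back$cells, `[[`, "boundary"))
  expect_equal(dim(b1), dim(b2))
  expect_close(b1, b2, 1e-9)
})

test_that("four unit squares meet in one 4-fold vertex; disjoint squares do not", {
  sq <- function(x0, y0) cbind(c(x0, x0 + 1, x0 + 1, x0),
                               c(y0, y0, y0 + 1, y0 + 1))
  mesh <- mesh_from_polygons(list(sq(0, 0), sq(1, 0), sq(0, 1), sq(1, 1)),
                             snap_tol_um = 1e-9)
  expect_length(mesh$vertices, 1)
  expect_equal(mesh$vertices[[1]]$order, 4L)
  expect_equal(nrow(mesh$adjacency), 4)

  far <- mesh_from_polygons(list(sq(0, 0), sq(5, 5)), snap_tol_um = 1e-9)
  expect_equal(nrow(far$adjacency), 0)
  expect_length(far$vertices, 0)
})

test_that("jitter below the snap tolerance preserves polygon-mesh topology", {
  sq <- function(x0, y0) cbind(c(x0, x0 + 1, x0 + 1, x0),
                               c(y0, y0, y0 + 1, y0 + 1))
  grid <- list()
  for (i in 0:2) for (j in 0:2) grid[[length(grid) + 1]] <- sq(i, j)
  ref <- mesh_from_polygons(grid, snap_tol_um = 1e-9)
  set.seed(42)
  jit <- lapply(grid, function(p) p + matrix(runif(8, -0.01, 0.01), 4, 2))
  got <- mesh_from_polygons(jit, snap_tol_um = 0.05)
  ordv <- function(m) unname(sort(vapply(m$vertices, `[[`, integer(1),
                                         "order")))
  expect_equal(ordv(got), ordv(ref))
  key <- function(m) paste(m$adjacency$cell_a, m$adjacency$cell_b)
  expect_setequal(key(got), key(ref))
})

test_that("overlapping polygon interiors beyond tolerance are rejected with ids", {
  a <- rect_polygon(2, 2, c(0, 0))
  b <- rect_polygon(2, 2, c(1, 0))   # overlaps half of a
  expect_error(mesh_from_polygons(list(a, b), snap_tol_um = 0.01),
               "overlap")
})

test_that("read_inputs validates co-registration and landmark files", {
  tis <- cached_tissue(1)
  dir <- tempfile(); dir.create(dir)
  write_tissue(tis, dir)
  # channel with wrong shape
  bad <- pixel_grid(matrix(0, 10, 10), tis$labels$pixel_size, "intensity")
  write_tiff_grid(bad, file.path(dir, "bad.tif"))
  expect_error(
    read_inputs(labels = file.path(dir, "labels.tif"),
                pixel_size = tis$labels$pixel_size,
                channels = list(A = file.path(dir, "bad.tif"))),
    "co-registered")
  # landmark file with 3 points
  lm3 <- utils::read.csv(file.path(dir, "landmarks.csv"))[1:3, ]
  utils::write.csv(lm3, file.path(dir, "lm3.csv"), row.names = FALSE)
  expect_error(read_landmarks_csv(file.path(dir, "lm3.csv")), "lm4")
})

test_that("label raster round-trips through TIFF", {
  tis <- cached_tissue(1)
  f <- tempfile(fileext = ".tif")
  write_tiff_grid(tis$labels, f)
  back <- read_tiff_grid(f, tis$labels$pixel_size, "labels")
  expect_identical(back$values, tis$labels$values)
})
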