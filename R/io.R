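# Readers and writers for the package's standard file formats: label and
# intensity TIFFs, GeoJSON meshes, and CSV tables for outlines, landmarks,
# AVJ/midline and per-cell results. All coordinates are micrometres in one
# shared y-up frame.

#' Read an outline CSV
#'
#' Expected columns `x_um,y_um` (ordered along the trace).
#'
#' @param path CSV path.
#' @return a `traced_outline`.
#' @export
read_outline_csv <- function(path) {
  d <- read_checked_csv(path, c("x_um", "y_um"))
  traced_outline(cbind(d$x_um, d$y_um))
}

#' Write an outline CSV
#' @param outline a `traced_outline`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(outline, path) {
  utils::write.csv(data.frame(x_um = outline$points[, 1],
                              y_um = outline$points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a landmarks CSV
#'
#' Expected columns `name,x_um,y_um` with names `lm1`..`lm4`.
#'
#' @param path CSV path.
#' @return data.frame with the four landmarks in order.
#' @export
read_landmarks_csv <- function(path) {
  d <- read_checked_csv(path, c("name", "x_um", "y_um"))
  need <- paste0("lm", 1:4)
  if (!all(need %in% d$name))
    stopf("expected 4 landmarks %s in %s; missing: %s",
          paste(need, collapse = ","), path,
          paste(setdiff(need, d$name), collapse = ","))
  d[match(need, d$name), , drop = FALSE]
}

#' Write a landmarks CSV
#' @param landmarks data.frame `name,x_um,y_um`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  utils::write.csv(landmarks[, c("name", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an AVJ/midline CSV
#'
#' Expected rows named `avj_p1`, `avj_p2` (points) and `midline`
#' (direction vector), columns `name,x_um,y_um`.
#'
#' @param path CSV path.
#' @return list with `avj_p1`, `avj_p2`, `midline`.
#' @export
read_avj_csv <- function(path) {
  d <- read_checked_csv(path, c("name", "x_um", "y_um"))
  need <- c("avj_p1", "avj_p2", "midline")
  if (!all(need %in% d$name))
    stopf("expected rows %s in %s; missing: %s",
          paste(need, collapse = ","), path,
          paste(setdiff(need, d$name), collapse = ","))
  g <- function(nm) as.numeric(d[d$name == nm, c("x_um", "y_um")][1, ])
  list(avj_p1 = g("avj_p1"), avj_p2 = g("avj_p2"), midline = g("midline"))
}

read_checked_csv <- function(path, need) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stopf("malformed CSV %s: %s", path,
                                          conditionMessage(e)))
  if (!all(need %in% names(d)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ","))
  d
}

#' Read all standard inputs of a run
#'
#' Loads the segmentation (label TIFF or mesh GeoJSON), optional intensity
#' channels (co-registered with the labels), the traced outline, the
#' landmark set, and an optional AVJ/midline file, converting everything to
#' micrometres in one shared frame.
#'
#' @param labels path to a label TIFF (or NULL when `mesh` is given).
#' @param pixel_size um per pixel for rasters.
#' @param mesh path to a GeoJSON mesh (alternative to `labels`).
#' @param channels named character vector/list of intensity TIFF paths.
#' @param outline path to the outline CSV.
#' @param landmarks path to the landmarks CSV.
#' @param avj optional path to the AVJ/midline CSV.
#' @param merge_tol_um vertex merge tolerance for raster meshes (default
#'   one pixel diagonal).
#' @return list with `mesh`, `labels` (or NULL), `channels` (list of
#'   `pixel_grid`s), `outline`, `landmarks`, `avj`.
#' @export
read_inputs <- function(labels = NULL, pixel_size = NULL, mesh = NULL,
                        channels = NULL, outline = NULL, landmarks = NULL,
                        avj = NULL, merge_tol_um = NULL) {
  if (is.null(labels) && is.null(mesh))
    stopf("either a label raster or a mesh file is required")
  lab_grid <- NULL
  if (!is.null(labels)) {
    if (is.null(pixel_size)) stopf("pixel_size is required with a label raster")
    lab_grid <- read_tiff_grid(labels, pixel_size, "labels")
    msh <- mesh_from_labels(lab_grid, merge_tol_um = merge_tol_um)
  } else {
    msh <- read_mesh_geojson(mesh)
  }
  chans <- list()
  if (!is.null(channels)) {
    for (nm in names(channels)) {
      ch <- read_tiff_grid(channels[[nm]], pixel_size %||% 1, "intensity")
      if (!is.null(lab_grid) &&
          (!all(dim(ch$values) == dim(lab_grid$values)) ||
             ch$pixel_size != lab_grid$pixel_size))
        stopf("channel '%s' is not co-registered with the labels", nm)
      chans[[nm]] <- ch
    }
  }
  list(mesh = msh,
       labels = lab_grid,
       channels = chans,
       outline = if (!is.null(outline)) read_outline_csv(outline),
       landmarks = if (!is.null(landmarks)) read_landmarks_csv(landmarks),
       avj = if (!is.null(avj)) read_avj_csv(avj))
}

#' Write all artefacts of a synthetic tissue to a directory
#'
#' Emits the label TIFF, optional channel TIFFs, mesh GeoJSON, outline and
#' landmark CSVs, and the ground-truth manifest JSON.
#'
#' @param tissue result of [generate_tissue()].
#' @param dir output directory (created if needed).
#' @param channels optional result of [generate_channels()].
#' @return the directory, invisibly.
#' @export
write_tissue <- function(tissue, dir, channels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tiff_grid(tissue$labels, file.path(dir, "labels.tif"))
  write_mesh_geojson(tissue$mesh, file.path(dir, "mesh.geojson"))
  write_outline_csv(tissue$outline, file.path(dir, "outline.csv"))
  write_landmarks_csv(tissue$landmarks, file.path(dir, "landmarks.csv"))
  if (!is.null(channels)) {
    write_tiff_grid(channels$A, file.path(dir, "channel_A.tif"))
    write_tiff_grid(channels$B, file.path(dir, "channel_B.tif"))
  }
  truth <- tissue$truth
  truth$landmarks <- as.data.frame(truth$landmarks)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", na = "null"),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}
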