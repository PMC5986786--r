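# End-to-end orchestration: a run configuration, the full measurement
# pipeline, and a deterministic report (per-analysis CSV tables plus a
# summary JSON that echoes every numeric knob used).

#' Build a run configuration
#'
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults. The configuration is serialised into every report.
#'
#' @param ... configuration values: `labels`, `pixel_size`, `mesh`,
#'   `channels`, `outline`, `landmarks`, `avj` (input paths);
#'   `merge_tol_um`, `exclude_boundary_cells`, `convention`, `smooth`,
#'   `width_px`, `margin`, `radius_um`, `k_sigma`, `min_n` (analysis
#'   knobs); `out_dir`, `seed`, `verbose`.
#' @return a `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(labels = NULL, pixel_size = NULL, mesh = NULL,
                   channels = NULL, outline = NULL, landmarks = NULL,
                   avj = NULL,
                   merge_tol_um = NULL, exclude_boundary_cells = FALSE,
                   convention = "normal", smooth = TRUE,
                   width_px = 10, margin = 0.2, radius_um = 1.5,
                   k_sigma = 2, min_n = 10,
                   out_dir = NULL, seed = 1L, verbose = FALSE)
  given <- list(...)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, given, keep.null = TRUE)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full measurement pipeline
#'
#' Reads (or accepts pre-loaded) inputs, builds the mesh, measures cell
#' shapes, detects transition states, fits the outline model, assigns
#' regions, computes axial angles and their circular statistics, and -- when
#' channels and an AVJ file are present -- co-localisation at transition
#' states and the looping angle. Writes CSVs and a summary JSON when
#' `out_dir` is set; identical inputs and configuration give identical
#' reports.
#'
#' @param config a `run_config`.
#' @param inputs optional pre-loaded inputs (as from [read_inputs()] or a
#'   [generate_tissue()] result); when NULL, inputs are read from the paths
#'   in `config`.
#' @return a `heart_report` list.
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(fmt, ...) if (isTRUE(config$verbose))
    message(sprintf(fmt, ...))
  if (is.null(inputs)) {
    inputs <- read_inputs(labels = config$labels,
                          pixel_size = config$pixel_size,
                          mesh = config$mesh, channels = config$channels,
                          outline = config$outline,
                          landmarks = config$landmarks, avj = config$avj,
                          merge_tol_um = config$merge_tol_um)
  } else if (!is.null(inputs$truth)) {
    # a generate_tissue() result: adapt field names
    inputs <- list(mesh = inputs$mesh, labels = inputs$labels,
                   channels = inputs$channels %||% list(),
                   outline = inputs$outline,
                   landmarks = data.frame(name = paste0("lm", 1:4),
                                          x_um = inputs$landmarks$x_um,
                                          y_um = inputs$landmarks$y_um),
                   avj = inputs$avj)
  }
  mesh <- inputs$mesh
  log_msg("mesh: %d cells", length(mesh$cells))

  outline_model <- NULL
  if (!is.null(inputs$outline) && !is.null(inputs$landmarks)) {
    smoothed <- smooth_outline(inputs$outline)
    landmarks <- place_landmarks(smoothed, inputs$landmarks)
    partition <- partition_segments(smoothed, landmarks)
    mesh <- assign_cell_regions(mesh, partition)
    outline_model <- list(smoothed = smoothed, landmarks = landmarks,
                          partition = partition)
  }

  shapes <- measure_cells(mesh, smooth = config$smooth)
  shapes$region <- vapply(mesh$cells, function(cl)
    cl$region %||% NA_character_, character(1))
  ts <- detect_transition_states(mesh)
  freq <- ts_frequency(mesh,
                       exclude_boundary_cells = config$exclude_boundary_cells)

  angles <- NULL; angle_report <- NULL; region_summary <- NULL
  if (!is.null(outline_model)) {
    angles <- cell_axial_angles(mesh, outline_model$smoothed, shapes,
                                convention = config$convention)
    angle_report <- region_angle_report(angles, min_n = config$min_n)
    region_summary <- summarise_regions(shapes)$table
  }

  looping <- NULL
  if (!is.null(inputs$avj)) {
    looping <- list(
      angle_deg = looping_angle(inputs$avj$avj_p1, inputs$avj$avj_p2,
                                inputs$avj$midline))
  }

  report <- structure(list(
    shapes = shapes, ts = ts, ts_summary = freq,
    region_summary = region_summary, angles = angles,
    angle_report = angle_report, looping = looping,
    outline_model = outline_model,
    config = config,
    version = as.character(utils::packageVersion("cardiomorph"))),
    class = "heart_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.heart_report <- function(x, ...) {
  cat("== cardiomorph report ==\n")
  cat(sprintf("Cells measured: %d\n", nrow(x$shapes)))
  print(x$ts_summary)
  if (!is.null(x$region_summary)) {
    cat("Region shape summary:\n")
    print(x$region_summary, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$angle_report)) {
    cat(sprintf("Axial angles (%s convention):\n", x$config$convention))
    print(x$angle_report[, c("region", "n", "mean_axis_deg", "R_bar",
                             "rayleigh_p")], row.names = FALSE, digits = 4)
  }
  if (!is.null(x$looping))
    cat(sprintf("Looping angle: %.1f deg\n", x$looping$angle_deg))
  invisible(x)
}

#' Write a report to a directory
#'
#' Per-analysis CSVs plus `summary.json` (counts, means, circular
#' statistics, looping angle, full configuration echo and package
#' version). Deterministic for identical reports.
#'
#' @param report a `heart_report`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$shapes, file.path(dir, "cell_shapes.csv"),
                   row.names = FALSE)
  write_ts_csv(report$ts, file.path(dir, "transition_states.csv"))
  if (!is.null(report$angles))
    utils::write.csv(report$angles, file.path(dir, "cell_angles.csv"),
                     row.names = FALSE)
  if (!is.null(report$angle_report))
    utils::write.csv(report$angle_report, file.path(dir, "region_angles.csv"),
                     row.names = FALSE)
  if (!is.null(report$region_summary))
    utils::write.csv(report$region_summary, file.path(dir, "region_shapes.csv"),
                     row.names = FALSE)
  cfg <- report$config
  summ <- list(
    n_cells = nrow(report$shapes),
    ts = list(n = report$ts_summary$n_ts,
              per_100 = report$ts_summary$ts_per_100,
              by_kind = as.list(report$ts_summary$by_kind),
              n_cells_counted = report$ts_summary$n_cells_counted),
    looping_angle_deg = if (!is.null(report$looping))
      report$looping$angle_deg,
    settings = cfg[setdiff(names(unclass(cfg)), c("out_dir", "verbose"))],
    version = report$version)
  writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             file.path(dir, "summary.json"))
  invisible(dir)
}

#' Plot a measured tissue
#'
#' Cell boundaries coloured by region with transition states overlaid;
#' a quick visual check of a run.
#'
#' @param x a `heart_report`.
#' @param mesh the measured `cell_mesh` (boundaries are not stored in the
#'   report tables).
#' @param ... passed to `plot.default`.
#' @return invisibly, `x`.
#' @export
plot_report <- function(x, mesh, ...) {
  regs <- vapply(mesh$cells, function(cl) cl$region %||% NA_character_,
                 character(1))
  pal <- grDevices::hcl.colors(max(1, length(unique(stats::na.omit(regs)))),
                               "Dark 3")
  names(pal) <- unique(stats::na.omit(regs))
  xy <- do.call(rbind, lapply(mesh$cells, `[[`, "boundary"))
  graphics::plot(xy[, 1], xy[, 2], type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  for (cl in mesh$cells) {
    b <- rbind(cl$boundary, cl$boundary[1, ])
    col <- if (!is.na(cl$region %||% NA)) pal[[cl$region]] else "grey60"
    graphics::lines(b[, 1], b[, 2], col = col)
  }
  if (nrow(x$ts) > 0)
    graphics::points(x$ts$x_um, x$ts$y_um, pch = 19, col = "red", cex = 0.8)
  invisible(x)
}
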