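# Transition states: junction vertices where four (T1) or more (rosette)
# cells converge onto a single shared boundary point, the intermediates of
# cell neighbour exchange in a single-layered epithelium.

#' Detect transition states on a mesh
#'
#' All junction vertices of order >= `min_order`, in deterministic
#' (position-lexicographic) order.
#'
#' @param mesh a `cell_mesh`.
#' @param min_order minimum vertex order, default 4.
#' @return data.frame with `ts_id`, `x_um`, `y_um`, `order`, `kind`
#'   ("T1" for order 4, "rosette" above) and an `incident` list-column of
#'   incident cell ids. Zero rows when no transition state exists.
#' @export
detect_transition_states <- function(mesh, min_order = 4L) {
  stopifnot(inherits(mesh, "cell_mesh"))
  ords <- vapply(mesh$vertices, `[[`, integer(1), "order")
  sel <- mesh$vertices[ords >= min_order]
  if (length(sel) == 0) {
    return(data.frame(ts_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), order = integer(0),
                      kind = character(0),
                      incident = I(list())))
  }
  pos <- t(vapply(sel, `[[`, numeric(2), "position"))
  o <- order(pos[, 1], pos[, 2])
  sel <- sel[o]; pos <- pos[o, , drop = FALSE]
  ords <- vapply(sel, `[[`, integer(1), "order")
  data.frame(ts_id = seq_along(sel),
             x_um = pos[, 1], y_um = pos[, 2],
             order = ords,
             kind = ifelse(ords == 4L, "T1", "rosette"),
             incident = I(lapply(sel, `[[`, "incident_cells")))
}

#' Transition-state frequency per 100 cells
#'
#' When `exclude_boundary_cells` is set (the default), cells at the image
#' edge or tissue rim are excluded from the denominator, and transition
#' states all of whose incident cells are boundary cells are excluded from
#' the numerator; this avoids counting vertices created artificially by the
#' image edge.
#'
#' @param mesh a `cell_mesh`.
#' @param exclude_boundary_cells logical, default TRUE.
#' @param min_order minimum vertex order counted, default 4.
#' @return a `ts_summary` list: `n_cells_counted`, `n_ts`, `ts_per_100`,
#'   `by_kind`, `settings`.
#' @export
ts_frequency <- function(mesh, exclude_boundary_cells = TRUE, min_order = 4L) {
  ts <- detect_transition_states(mesh, min_order)
  bnd <- cell_is_boundary(mesh)
  ids <- cell_ids(mesh)
  if (exclude_boundary_cells) {
    n_cells <- sum(!bnd)
    if (n_cells == 0) stopf("no countable cells after boundary exclusion")
    keep <- vapply(ts$incident, function(inc) {
      any(!bnd[match(inc, ids)])
    }, logical(1))
    ts <- ts[keep, , drop = FALSE]
  } else {
    n_cells <- length(ids)
    if (n_cells == 0) stopf("no countable cells")
  }
  by_kind <- c(T1 = sum(ts$kind == "T1"), rosette = sum(ts$kind == "rosette"))
  out <- list(n_cells_counted = n_cells,
              n_ts = nrow(ts),
              ts_per_100 = 100 * nrow(ts) / n_cells,
              by_kind = by_kind,
              settings = list(exclude_boundary_cells = exclude_boundary_cells,
                              min_order = min_order))
  class(out) <- "ts_summary"
  out
}

#' @export
print.ts_summary <- function(x, ...) {
  cat(sprintf(
    "Transition states: %d (%d T1, %d rosette) over %d cells -> %.2f per 100 cells\n",
    x$n_ts, x$by_kind[["T1"]], x$by_kind[["rosette"]],
    x$n_cells_counted, x$ts_per_100))
  cat(sprintf("  (boundary cells %s)\n",
              if (x$settings$exclude_boundary_cells) "excluded" else "included"))
  invisible(x)
}

#' One-way ANOVA across groups of per-heart frequencies
#'
#' Classical one-way ANOVA (via `aov`) with Bonferroni-adjusted pairwise
#' comparisons using the pooled error variance, a convenience mirror of the
#' group-level testing style used for per-heart transition-state rates.
#'
#' @param values numeric vector of per-heart values.
#' @param groups factor or character vector of group labels, same length.
#' @return list with `F`, `p`, `df`, and `pairwise` (data.frame of group
#'   pairs with Bonferroni-adjusted p-values, `p_adj = min(1, p * m)`).
#' @export
group_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stopf("need >= 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  av <- summary(fit)[[1]]
  Fv <- av[["F value"]][1]
  pv <- av[["Pr(>F)"]][1]
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                               pool.sd = TRUE)
  m <- sum(!is.na(pw$p.value))
  idx <- which(!is.na(pw$p.value), arr.ind = TRUE)
  pairwise <- data.frame(
    group_a = rownames(pw$p.value)[idx[, 1]],
    group_b = colnames(pw$p.value)[idx[, 2]],
    p_raw = pw$p.value[idx],
    p_adj = pmin(1, pw$p.value[idx] * m))
  list(F = Fv, p = pv,
       df = c(between = av$Df[1], within = av$Df[2]),
       pairwise = pairwise)
}

#' Write a transition-state table as CSV
#'
#' Columns `ts_id,x_um,y_um,order,kind`.
#'
#' @param ts data.frame from [detect_transition_states()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ts_csv <- function(ts, path) {
  utils::write.csv(ts[, c("ts_id", "x_um", "y_um", "order", "kind")],
                   path, row.names = FALSE)
  invisible(path)
}
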