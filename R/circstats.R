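# Axial circular statistics. Orientations defined modulo 180 degrees are
# analysed by angle doubling: the doubled angles live on the full circle,
# where the mean resultant length and the Rayleigh test of uniformity apply;
# the mean axis is half the doubled-angle mean direction.

#' Rayleigh test p-value (series approximation)
#'
#' Classical large-sample series for the Rayleigh statistic `Z = n * R_bar^2`:
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2)]`,
#' clamped to (0, 1].
#'
#' @param Z Rayleigh statistic.
#' @param n sample size.
#' @return p-value in (0, 1].
#' @export
rayleigh_p_series <- function(Z, n) {
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Monte-Carlo Rayleigh p-value
#'
#' Simulated null of `Z = n * R_bar^2` under circular uniformity; useful as
#' an exact-by-simulation alternative to the series at small n.
#'
#' @param Z observed statistic.
#' @param n sample size.
#' @param n_mc number of Monte-Carlo replicates.
#' @return p-value estimate (add-one estimator, in (0, 1]).
#' @export
rayleigh_p_mc <- function(Z, n, n_mc = 1e4) {
  phi <- matrix(stats::runif(n_mc * n, 0, 2 * pi), n_mc, n)
  Zs <- (rowSums(cos(phi))^2 + rowSums(sin(phi))^2) / n
  (1 + sum(Zs >= Z)) / (n_mc + 1)
}

#' Axial circular summary with Rayleigh test on doubled angles
#'
#' Angles are doubled (`phi = 2 * theta`), giving the mean resultant length
#' `R_bar`, circular variance `1 - R_bar`, mean axis
#' `atan2(S, C) / 2` mapped to [0, 180), Rayleigh `Z = n * R_bar^2` and the
#' series p-value. `NA` angles are excluded with a logged count.
#'
#' @param angles_deg axial angles in degrees (any 180-periodic
#'   representation).
#' @param p_method "series" (default) or "mc".
#' @param n_mc Monte-Carlo replicates when `p_method = "mc"`.
#' @param mean_axis_tol `R_bar` below which the mean axis is reported `NA`.
#' @return a `circ_summary`: `n`, `n_na`, `mean_axis_deg` in [0, 180),
#'   `mean_axis_pm90` on (-90, 90], `R_bar`, `circ_variance`, `rayleigh_Z`,
#'   `rayleigh_p`.
#' @export
axial_summary <- function(angles_deg, p_method = c("series", "mc"),
                          n_mc = 1e4, mean_axis_tol = 1e-12) {
  p_method <- match.arg(p_method)
  n_na <- sum(is.na(angles_deg))
  a <- angles_deg[!is.na(angles_deg)]
  n <- length(a)
  if (n == 0) stopf("no non-missing angles")
  phi <- deg2rad(2 * a)
  C <- sum(cos(phi)); S <- sum(sin(phi))
  R_bar <- sqrt(C^2 + S^2) / n
  Z <- n * R_bar^2
  mean_axis <- if (R_bar > mean_axis_tol) {
    fold_axis180(rad2deg(atan2(S, C) / 2))
  } else NA_real_
  p <- switch(p_method,
              series = rayleigh_p_series(Z, n),
              mc = rayleigh_p_mc(Z, n, n_mc))
  structure(list(n = n, n_na = n_na,
                 mean_axis_deg = mean_axis,
                 mean_axis_pm90 = if (is.na(mean_axis)) NA_real_
                                  else fold_axial(mean_axis),
                 R_bar = R_bar,
                 circ_variance = 1 - R_bar,
                 rayleigh_Z = Z,
                 rayleigh_p = p,
                 p_method = p_method),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf(
    "Axial summary: n = %d (%d NA), mean axis = %s deg, R_bar = %.4f, Z = %.3f, p = %.3g\n",
    x$n, x$n_na,
    if (is.na(x$mean_axis_deg)) "undefined" else sprintf("%.2f", x$mean_axis_deg),
    x$R_bar, x$rayleigh_Z, x$rayleigh_p))
  invisible(x)
}

#' Per-region axial angle report
#'
#' [axial_summary()] per region; regions with fewer than `min_n` angles are
#' flagged `low_n`.
#'
#' @param angles data.frame with columns `region` and `angle_deg` (e.g. from
#'   [cell_axial_angles()]).
#' @param min_n flagging threshold (default 10).
#' @param p_method passed to [axial_summary()].
#' @return data.frame `region,n,n_na,mean_axis_deg,mean_axis_pm90,R_bar,
#'   circ_variance,rayleigh_Z,rayleigh_p,low_n`.
#' @export
region_angle_report <- function(angles, min_n = 10, p_method = "series") {
  stopifnot(all(c("region", "angle_deg") %in% names(angles)))
  angles <- angles[!is.na(angles$region), , drop = FALSE]
  rows <- lapply(split(angles, angles$region), function(d) {
    s <- axial_summary(d$angle_deg, p_method = p_method)
    data.frame(region = d$region[1], n = s$n, n_na = s$n_na,
               mean_axis_deg = s$mean_axis_deg,
               mean_axis_pm90 = s$mean_axis_pm90,
               R_bar = s$R_bar, circ_variance = s$circ_variance,
               rayleigh_Z = s$rayleigh_Z, rayleigh_p = s$rayleigh_p,
               low_n = s$n < min_n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
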