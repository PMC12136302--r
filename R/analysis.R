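#' Unit calibration between model and physical units
#'
#' The model is expressed in nondimensional grid and time units. A
#' calibration assigns a physical length to one grid unit and a physical
#' duration to one time unit so that simulated propagation speeds can be
#' reported in mm/min, the unit in which experimental CSD speeds are
#' quoted.
#'
#' @param mm_per_grid_unit Physical length of one grid-coordinate unit
#'   (mm, > 0).
#' @param seconds_per_time_unit Physical duration of one model time unit
#'   (s, > 0).
#' @return An object of class \code{"unit_calibration"}.
#' @export
unit_calibration <- function(mm_per_grid_unit, seconds_per_time_unit = 1) {
  if (!is.finite(mm_per_grid_unit) || mm_per_grid_unit <= 0)
    stop("unit_calibration: 'mm_per_grid_unit' must be > 0", call. = FALSE)
  if (!is.finite(seconds_per_time_unit) || seconds_per_time_unit <= 0)
    stop("unit_calibration: 'seconds_per_time_unit' must be > 0",
         call. = FALSE)
  structure(list(mm_per_grid_unit = mm_per_grid_unit,
                 seconds_per_time_unit = seconds_per_time_unit),
            class = "unit_calibration")
}

# model speed (grid units per time unit) -> mm/min
speed_to_mm_per_min <- function(v_model, cal) {
  stopifnot(inherits(cal, "unit_calibration"))
  v_model * cal$mm_per_grid_unit / cal$seconds_per_time_unit * 60
}

#' Detect the rightward wavefront in one snapshot
#'
#' Returns the largest node index at or beyond the center whose
#' excitatory potential reaches the threshold. Propagation is symmetric
#' about the centered stimulus, so tracking the rightward front suffices.
#'
#' @param ve_snapshot Per-node excitatory potentials, length N.
#' @param threshold Wavefront voltage threshold.
#' @param grid A \code{\link{build_grid}} object.
#' @return 1-based node index of the front, or \code{NA_integer_} when no
#'   node at or beyond the center is suprathreshold.
#' @export
detect_wavefront <- function(ve_snapshot, threshold, grid) {
  stopifnot(inherits(grid, "csd_grid"))
  if (length(ve_snapshot) != grid$N)
    stop("detect_wavefront: snapshot length does not match grid",
         call. = FALSE)
  ctr <- grid_center(grid)
  idx <- which(ve_snapshot >= threshold)
  idx <- idx[idx >= ctr]
  if (!length(idx)) NA_integer_ else max(idx)
}

# front node index at every recorded time (NA where no front)
front_positions <- function(traj, threshold) {
  vapply(seq_along(traj$times), function(i)
    detect_wavefront(traj$ve[i, ], threshold, traj$grid), integer(1))
}

#' Propagation speed of the simulated wave
#'
#' The primary estimator divides the distance between the outermost
#' suprathreshold node in the final snapshot and the axis center by the
#' final time: \code{v = hx * (nth - N %/% 2) / tF}. Because it uses only
#' the final front position it folds any initiation latency into the
#' average; a secondary least-squares estimate of the front-position
#' slope over the second half of the run is reported alongside for
#' diagnostics, and the two agree closely once the wave travels at its
#' constant asymptotic velocity.
#'
#' @param traj A \code{\link{simulate_field}} trajectory.
#' @param threshold Wavefront voltage threshold.
#' @param cal A \code{\link{unit_calibration}} object.
#' @return An object of class \code{"csd_speed"}: fields \code{nth}
#'   (0-based front offset is \code{nth - center}), \code{threshold},
#'   \code{t_final}, \code{speed_model_units}, \code{speed_mm_per_min},
#'   and \code{front_slope_model_units} (the diagnostic slope, \code{NA}
#'   if fewer than three front points exist).
#' @export
propagation_speed <- function(traj, threshold, cal) {
  stopifnot(inherits(traj, "csd_trajectory"),
            inherits(cal, "unit_calibration"))
  n_rec <- length(traj$times)
  if (n_rec < 1) stop("propagation_speed: empty trajectory", call. = FALSE)
  ctr <- grid_center(traj$grid)
  tF <- traj$times[n_rec]
  nth <- detect_wavefront(traj$ve[n_rec, ], threshold, traj$grid)
  if (is.na(nth))
    stop("propagation_speed: no suprathreshold front at the final time; ",
         "the wave did not form or died out", call. = FALSE)
  v_model <- traj$grid$hx * (nth - ctr) / tF

  # diagnostic: front-position slope over the second half of the run
  fp <- front_positions(traj, threshold)
  sel <- which(!is.na(fp) & traj$times >= tF / 2)
  slope <- NA_real_
  if (length(sel) >= 3) {
    tt <- traj$times[sel]
    xx <- (fp[sel] - ctr) * traj$grid$hx
    slope <- unname(stats::coef(stats::lm(xx ~ tt))[2])
  }

  structure(list(nth = nth, threshold = threshold, t_final = tF,
                 speed_model_units = v_model,
                 speed_mm_per_min = speed_to_mm_per_min(v_model, cal),
                 front_slope_model_units = slope,
                 calibration = cal),
            class = "csd_speed")
}

#' @export
print.csd_speed <- function(x, ...) {
  cat(sprintf(paste0("CSD propagation speed: %.4f grid units per time unit ",
                     "(%.3f mm/min)\n"),
              x$speed_model_units, x$speed_mm_per_min))
  cat(sprintf("  front node %d at tF = %g (threshold %g); slope diagnostic %s\n",
              x$nth, x$t_final, x$threshold,
              if (is.na(x$front_slope_model_units)) "n/a"
              else sprintf("%.4f", x$front_slope_model_units)))
  invisible(x)
}

#' Extrema of the excitatory potential at one node
#'
#' Maximum and minimum of \code{ve} at a probe node over recorded times,
#' after discarding an initial fraction of the horizon as transient.
#'
#' @param traj A trajectory.
#' @param node 1-based node index.
#' @param discard_fraction Fraction of the horizon to drop from the start
#'   (in \[0, 1)).
#' @return Named numeric vector \code{c(max_ve, min_ve)}.
#' @export
node_extrema <- function(traj, node, discard_fraction = 0.2) {
  stopifnot(inherits(traj, "csd_trajectory"))
  if (node < 1 || node > traj$grid$N)
    stop("node_extrema: 'node' out of range", call. = FALSE)
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("node_extrema: 'discard_fraction' must be in [0, 1)", call. = FALSE)
  tF <- traj$times[length(traj$times)]
  keep <- traj$times >= discard_fraction * tF
  if (!any(keep))
    stop("node_extrema: no snapshots after the discard window", call. = FALSE)
  v <- traj$ve[keep, node]
  c(max_ve = max(v), min_ve = min(v))
}

#' Classify a run as propagating or quiescent
#'
#' A run counts as propagating when the final wavefront has covered at
#' least \code{reach_fraction} of the half-axis beyond the center.
#'
#' @param traj A trajectory.
#' @param threshold Wavefront voltage threshold.
#' @param reach_fraction Required fraction of the half-axis (in (0, 1\]).
#' @return \code{"propagating"} or \code{"quiescent"}.
#' @export
classify_regime <- function(traj, threshold, reach_fraction = 0.5) {
  stopifnot(inherits(traj, "csd_trajectory"))
  if (reach_fraction <= 0 || reach_fraction > 1)
    stop("classify_regime: 'reach_fraction' must be in (0, 1]", call. = FALSE)
  ctr <- grid_center(traj$grid)
  n_rec <- length(traj$times)
  nth <- detect_wavefront(traj$ve[n_rec, ], threshold, traj$grid)
  if (is.na(nth)) return("quiescent")
  half <- traj$grid$N - ctr
  if ((nth - ctr) >= reach_fraction * half) "propagating" else "quiescent"
}

#' Space-time matrix of one field
#'
#' @param traj A trajectory.
#' @param field One of \code{"ve"}, \code{"vi"}, \code{"k"}.
#' @return Matrix with rows = recorded times (rownames = times) and
#'   columns = nodes (colnames = grid coordinates).
#' @export
space_time_matrix <- function(traj, field = c("ve", "vi", "k")) {
  stopifnot(inherits(traj, "csd_trajectory"))
  field <- match.arg(field)
  m <- traj[[field]]
  rownames(m) <- format(traj$times, trim = TRUE)
  colnames(m) <- format(traj$grid$x, trim = TRUE)
  m
}

#' Space-time heatmap of a trajectory field
#'
#' Renders the space-time diagram of the chosen field (time on the
#' vertical axis, propagation axis on the horizontal) as an image plot.
#'
#' @param x A \code{csd_trajectory}.
#' @param field Which field to draw.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.csd_trajectory <- function(x, field = c("ve", "vi", "k"), ...) {
  field <- match.arg(field)
  m <- x[[field]]
  graphics::image(x = x$grid$x, y = x$times, z = t(m),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "position on propagation axis Q",
                  ylab = "time (model units)",
                  main = sprintf("space-time diagram: %s", field), ...)
  invisible(x)
}
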