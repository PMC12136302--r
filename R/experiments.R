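#' Experimental condition presets
#'
#' Maps the experimental manipulations of GABAergic neurons onto
#' parameter overrides of the calibrated control configuration:
#' \describe{
#'   \item{control}{no change (\code{c_ei = c_ii = 15}, \code{c2 = 15}).}
#'   \item{iso}{GABA-A agonist: inhibitory synaptic weights raised
#'     (default \code{c_ei = c_ii = 20}).}
#'   \item{gbz}{GABA-A antagonist: inhibitory synaptic weights reduced to
#'     \code{c_ei = c_ii = 11}.}
#'   \item{light}{optogenetic activation of GABAergic neurons: both their
#'     synaptic output and their spiking potassium load raised (defaults
#'     \code{c_ei = c_ii = 20}, \code{c2 = 20}).}
#'   \item{gbz_light}{combined antagonist plus light:
#'     \code{c_ei = c_ii = 10.5}, \code{c2 = 49}.}
#' }
#' Only \code{c_ei}, \code{c_ii} and \code{c2} are ever touched.
#'
#' @param name Condition name.
#' @param c_ei,c_ii,c2 Optional overrides of the preset defaults.
#' @return An object of class \code{"csd_condition"} carrying the
#'   parameter overrides.
#' @export
condition_preset <- function(name = c("control", "iso", "gbz", "light",
                                      "gbz_light"),
                             c_ei = NULL, c_ii = NULL, c2 = NULL) {
  name <- match.arg(name)
  ov <- switch(name,
    control   = list(),
    iso       = list(c_ei = 20, c_ii = 20),
    gbz       = list(c_ei = 11, c_ii = 11),
    light     = list(c_ei = 20, c_ii = 20, c2 = 20),
    gbz_light = list(c_ei = 10.5, c_ii = 10.5, c2 = 49))
  if (!is.null(c_ei)) ov$c_ei <- c_ei
  if (!is.null(c_ii)) ov$c_ii <- c_ii
  if (!is.null(c2)) ov$c2 <- c2
  bad <- setdiff(names(ov), c("c_ei", "c_ii", "c2"))
  if (length(bad))
    stop("condition_preset: overrides may only touch c_ei, c_ii, c2",
         call. = FALSE)
  structure(list(name = name, overrides = ov), class = "csd_condition")
}

#' Apply a condition preset to a parameter record
#'
#' @param params The calibrated control \code{\link{csd_params}} record.
#' @param condition A \code{\link{condition_preset}} object or a
#'   condition name.
#' @return A new \code{csd_params} with the condition's overrides
#'   applied; \code{control} returns the record unchanged.
#' @export
apply_condition <- function(params, condition) {
  stopifnot(inherits(params, "csd_params"))
  if (is.character(condition)) condition <- condition_preset(condition)
  stopifnot(inherits(condition, "csd_condition"))
  if (!length(condition$overrides)) return(params)
  do.call(update_params, c(list(params), condition$overrides))
}

#' Unit calibration from a measured control speed
#'
#' Fixes one second per model time unit by convention and chooses the
#' physical length of a grid unit so that the measured control-run speed
#' converts exactly to the target speed in mm/min. Pure arithmetic; no
#' re-simulation.
#'
#' @param control_speed_model_units Control speed in grid units per model
#'   time unit (> 0).
#' @param target_mm_per_min Desired control speed in mm/min (> 0).
#' @param seconds_per_time_unit Physical duration of a model time unit.
#' @return A \code{\link{unit_calibration}}.
#' @export
calibrate_units <- function(control_speed_model_units, target_mm_per_min,
                            seconds_per_time_unit = 1) {
  if (!is.finite(control_speed_model_units) || control_speed_model_units <= 0)
    stop("calibrate_units: control speed must be > 0", call. = FALSE)
  if (!is.finite(target_mm_per_min) || target_mm_per_min <= 0)
    stop("calibrate_units: target speed must be > 0", call. = FALSE)
  mmgu <- target_mm_per_min * seconds_per_time_unit /
    (60 * control_speed_model_units)
  unit_calibration(mm_per_grid_unit = mmgu,
                   seconds_per_time_unit = seconds_per_time_unit)
}

#' Run one simulation under a full configuration
#'
#' Convenience wrapper: builds the grid and initial state from a resolved
#' configuration (see \code{\link{reference_config}}), applies an
#' optional condition, simulates, and returns the trajectory.
#'
#' @param config A resolved configuration list.
#' @param condition Optional condition name or preset.
#' @param ... Scalar parameter overrides applied after the condition
#'   (e.g. \code{c2 = 30}, \code{kv_star = 1.4}).
#' @return A \code{csd_trajectory}.
#' @export
run_config <- function(config, condition = NULL, ...) {
  config <- validate_config(config)
  params <- config_params(config)
  if (!is.null(condition)) params <- apply_condition(params, condition)
  dots <- list(...)
  if (length(dots)) params <- do.call(update_params, c(list(params), dots))
  grid <- build_grid(config$Lx, config$N)
  init <- initial_state(grid, c(config$ve0, config$vi0), config$k0, params)
  settings <- integration_settings(config$dt, config$t_final,
                                   config$record_every)
  stim <- stimulus_params(config$stim_amplitude, config$stim_center,
                          config$stim_width, config$stim_onset,
                          config$stim_duration)
  simulate_field(params, grid, init, settings, stim)
}

#' Speed of a configured run
#'
#' @param config A resolved configuration list.
#' @param condition Optional condition name or preset.
#' @param ... Scalar parameter overrides.
#' @return A \code{csd_speed}.
#' @export
config_speed <- function(config, condition = NULL, ...) {
  config <- validate_config(config)
  traj <- run_config(config, condition, ...)
  cal <- unit_calibration(config$mm_per_grid_unit,
                          config$seconds_per_time_unit)
  propagation_speed(traj, config$threshold, cal)
}

#' Sweep a parameter and measure the propagation speed at each value
#'
#' Runs one full simulation per value of the swept parameter(s) and
#' measures the wave speed. Runs in which no wave forms are recorded as
#' failures, not raised.
#'
#' @param config A resolved configuration list (the calibrated control
#'   record unless overridden).
#' @param param Name of the swept parameter, or a character vector of
#'   names swept jointly (e.g. \code{c("c_ei", "c_ii")}).
#' @param values Numeric vector of values (non-empty, finite).
#' @param condition Optional condition applied before the sweep override.
#' @return An object of class \code{"csd_sweep"}: data frame with columns
#'   \code{value}, \code{speed_model_units}, \code{speed_mm_per_min},
#'   \code{nth}, \code{t_final}, \code{regime}, plus the sweep metadata.
#' @export
sweep_speed <- function(config, param, values, condition = NULL) {
  config <- validate_config(config)
  if (!length(values) || any(!is.finite(values)))
    stop("sweep_speed: 'values' must be non-empty and finite", call. = FALSE)
  cal <- unit_calibration(config$mm_per_grid_unit,
                          config$seconds_per_time_unit)
  rows <- lapply(values, function(v) {
    ov <- stats::setNames(as.list(rep(v, length(param))), param)
    traj <- do.call(run_config, c(list(config, condition), ov))
    regime <- classify_regime(traj, config$threshold, config$reach_fraction)
    sp <- tryCatch(propagation_speed(traj, config$threshold, cal),
                   error = function(e) NULL)
    if (is.null(sp))
      data.frame(value = v, speed_model_units = NA_real_,
                 speed_mm_per_min = NA_real_, nth = NA_integer_,
                 t_final = max(traj$times), regime = regime)
    else
      data.frame(value = v, speed_model_units = sp$speed_model_units,
                 speed_mm_per_min = sp$speed_mm_per_min, nth = sp$nth,
                 t_final = sp$t_final, regime = regime)
  })
  out <- do.call(rbind, rows)
  structure(list(results = out, param = param,
                 condition = if (is.null(condition)) "control"
                             else if (is.character(condition)) condition
                             else condition$name,
                 config = config),
            class = "csd_sweep")
}

#' @export
print.csd_sweep <- function(x, ...) {
  cat(sprintf("Speed sweep over %s (%d values, base condition: %s)\n",
              paste(x$param, collapse = " = "), nrow(x$results),
              x$condition))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' @export
plot.csd_sweep <- function(x, ...) {
  r <- x$results
  graphics::plot(r$value, r$speed_mm_per_min, type = "b", pch = 16,
                 xlab = paste(x$param, collapse = " = "),
                 ylab = "propagation speed (mm/min)", ...)
  invisible(x)
}

#' Bifurcation scan over the potassium drive threshold
#'
#' Re-runs the field for each value of \code{kv_star}, records the
#' excitatory-potential extrema at a probe node and classifies the run as
#' quiescent or propagating. The transition point is the midpoint of the
#' last label change along the scan.
#'
#' @param config A resolved configuration list.
#' @param kv_values Strictly increasing vector of \code{kv_star} values.
#' @param probe 1-based probe node index; by default the node sitting at
#'   the classification reach line, so the probe's potential excursion
#'   mirrors the regime label: a propagating wave sweeps past it, a
#'   quiescent run leaves it at rest.
#' @param discard_fraction Transient fraction dropped by
#'   \code{\link{node_extrema}}.
#' @return An object of class \code{"csd_bifurcation"}: data frame with
#'   \code{kv_star}, \code{max_ve}, \code{min_ve}, \code{regime}; the
#'   estimated \code{transition}; and \code{multistable}, \code{TRUE}
#'   when more than one label change was seen (a warning is attached).
#' @export
bifurcation_scan <- function(config, kv_values, probe = NULL,
                             discard_fraction = 0.2) {
  config <- validate_config(config)
  if (is.unsorted(kv_values, strictly = TRUE))
    stop("bifurcation_scan: 'kv_values' must be strictly increasing",
         call. = FALSE)
  if (is.null(probe)) {
    g <- build_grid(config$Lx, config$N)
    ctr <- grid_center(g)
    probe <- ctr + as.integer(ceiling(config$reach_fraction * (g$N - ctr)))
  }
  rows <- lapply(kv_values, function(kv) {
    traj <- run_config(config, kv_star = kv)
    ex <- node_extrema(traj, probe, discard_fraction)
    regime <- classify_regime(traj, config$threshold, config$reach_fraction)
    data.frame(kv_star = kv, max_ve = ex[["max_ve"]],
               min_ve = ex[["min_ve"]], regime = regime)
  })
  out <- do.call(rbind, rows)
  lab <- out$regime == "propagating"
  changes <- which(lab[-1] != lab[-length(lab)])
  transition <- NA_real_
  multistable <- FALSE
  if (length(changes)) {
    last <- changes[length(changes)]
    transition <- (kv_values[last] + kv_values[last + 1]) / 2
    if (length(changes) > 1) {
      multistable <- TRUE
      warning("bifurcation_scan: more than one regime change across the ",
              "scan; possible multistability", call. = FALSE)
    }
  }
  structure(list(results = out, transition = transition,
                 multistable = multistable, probe = probe, config = config),
            class = "csd_bifurcation")
}

#' @export
print.csd_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation scan over kv_star (probe node %d)\n", x$probe))
  print(x$results, row.names = FALSE)
  if (is.na(x$transition))
    cat("  no regime change inside the scanned range\n")
  else
    cat(sprintf("  estimated quiescent/propagating transition: kv_star ~ %g\n",
                x$transition))
  invisible(x)
}

#' @export
plot.csd_bifurcation <- function(x, ...) {
  r <- x$results
  graphics::plot(r$kv_star, r$max_ve, pch = 16, col = "blue",
                 ylim = range(c(r$max_ve, r$min_ve)),
                 xlab = "kv_star", ylab = "ve extrema at probe node", ...)
  graphics::points(r$kv_star, r$min_ve, pch = 16, col = "red")
  if (!is.na(x$transition))
    graphics::abline(v = x$transition, lty = 2)
  graphics::legend("topright", legend = c("max ve", "min ve"),
                   col = c("blue", "red"), pch = 16, bty = "n")
  invisible(x)
}
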