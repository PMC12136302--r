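#' The frozen reference configuration
#'
#' Returns the versioned reference configuration of the package: the
#' calibrated control condition from which every experiment preset,
#' sweep and scan departs. The coupling weights and time constant are
#' the published control values (\code{c_ee = c_ie = 1},
#' \code{c_ei = c_ii = 15}, \code{c1 = c2 = 15}, \code{tau = 0.15});
#' the remaining entries (transfer-function shape, potassium thresholds,
#' production scale, grid, stimulus, integration step, wavefront
#' threshold, unit calibration) were fixed once against two calibration
#' anchors -- a control propagation speed of 2.2 mm/min and a
#' quiescent-to-propagating transition near \code{kv_star = 1.5} -- and
#' are not retuned thereafter.
#'
#' @return A named list of scalar configuration entries (a "resolved
#'   configuration"); see \code{\link{load_config}} for the file-based
#'   interface and \code{\link{config_params}} for conversion to a
#'   \code{\link{csd_params}} object.
#' @export
reference_config <- function() {
  list(
    # transfer functions
    beta_e = 2, h_e = -5.53,
    beta_i = 12, h_i = -4.88,
    k1_star = 1.25, k2_star = 1.55,
    # potassium drive
    beta_ve = 20, beta_vi = 20, kv_star = 1,
    # potassium production
    a = 1.42e-5, b = 11.85, c = 0.4, v_star = -3.58,
    # synaptic coupling and transport
    c_ee = 1, c_ei = 15, c_ie = 1, c_ii = 15,
    c1 = 15, c2 = 15, tau = 0.15, delta = 0.2635,
    # grid
    Lx = 40, N = 201,
    # baselines
    ve0 = -4.83, vi0 = -4.83, k0 = 0.5,
    # stimulus
    stim_amplitude = 2, stim_center = 0, stim_width = 1.5,
    stim_onset = 0, stim_duration = 0.3,
    # integration
    dt = 0.01, t_final = 16, record_every = 20,
    # analysis
    threshold = -0.5, reach_fraction = 0.33,
    # unit calibration (control speed 0.85 grid units/time -> 2.2 mm/min)
    mm_per_grid_unit = 0.0431372549, seconds_per_time_unit = 1
  )
}

# entries that must be positive / non-negative / integral
.cfg_positive <- c("beta_e", "beta_i", "beta_ve", "beta_vi", "a",
                   "k1_star", "k2_star", "tau", "Lx", "stim_width", "dt",
                   "t_final", "mm_per_grid_unit", "seconds_per_time_unit")
.cfg_nonneg <- c("b", "c", "c_ee", "c_ei", "c_ie", "c_ii", "c1", "c2",
                 "delta", "k0", "stim_amplitude", "stim_onset",
                 "stim_duration")

#' Validate a configuration
#'
#' Checks completeness (every reference key present, no unknown keys)
#' and every type invariant before any simulation starts. Partial
#' configurations are completed from \code{\link{reference_config}}.
#'
#' @param config A named list; missing entries are filled from the
#'   reference configuration.
#' @return The resolved, validated configuration list.
#' @export
validate_config <- function(config) {
  ref <- reference_config()
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("validate_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(ref, config)

  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1 &&
                  is.finite(v), logical(1))
  if (!all(num))
    stop("validate_config: non-scalar or non-finite entries: ",
         paste(names(cfg)[!num], collapse = ", "), call. = FALSE)
  for (nm in .cfg_positive)
    if (cfg[[nm]] <= 0)
      stop(sprintf("validate_config: '%s' must be > 0", nm), call. = FALSE)
  for (nm in .cfg_nonneg)
    if (cfg[[nm]] < 0)
      stop(sprintf("validate_config: '%s' must be >= 0", nm), call. = FALSE)
  if (cfg$k2_star <= cfg$k1_star)
    stop("validate_config: 'k2_star' must exceed k1_star", call. = FALSE)
  if (cfg$v_star <= max(cfg$h_e, cfg$h_i))
    stop("validate_config: 'v_star' must exceed the half-response voltages",
         call. = FALSE)
  if (cfg$k0 >= cfg$k1_star)
    stop("validate_config: 'k0' must be below k1_star", call. = FALSE)
  if (cfg$N < 3 || cfg$N != round(cfg$N))
    stop("validate_config: 'N' must be an integer >= 3", call. = FALSE)
  if (cfg$record_every < 1 || cfg$record_every != round(cfg$record_every))
    stop("validate_config: 'record_every' must be an integer >= 1",
         call. = FALSE)
  if (cfg$t_final < cfg$dt)
    stop("validate_config: 't_final' must be >= dt", call. = FALSE)
  if (cfg$reach_fraction <= 0 || cfg$reach_fraction > 1)
    stop("validate_config: 'reach_fraction' must be in (0, 1]", call. = FALSE)
  cfg
}

#' Build model parameters from a configuration
#'
#' @param config A resolved configuration (see
#'   \code{\link{validate_config}}).
#' @return A \code{\link{csd_params}} object.
#' @export
config_params <- function(config) {
  config <- validate_config(config)
  params_from_list(config)
}

#' Load a configuration file
#'
#' Reads a YAML configuration, fills every omitted field from the
#' reference configuration, and validates the result. An empty file
#' yields exactly the reference configuration. Unknown keys are errors,
#' not warnings.
#'
#' @param path Path to a YAML file.
#' @param echo_dir Optional directory; when given, the fully resolved
#'   configuration is echoed there as \code{resolved_config.yaml}.
#' @return The resolved configuration list.
#' @export
load_config <- function(path, echo_dir = NULL) {
  if (!file.exists(path))
    stop("load_config: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("load_config: configuration must be a YAML mapping", call. = FALSE)
  cfg <- validate_config(raw)
  if (!is.null(echo_dir)) {
    dir.create(echo_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(echo_dir, "resolved_config.yaml"))
  }
  cfg
}

#' Save and restore trajectories
#'
#' \code{write_trajectory} serializes a trajectory losslessly (R native
#' serialization, version 3); \code{read_trajectory} restores it and
#' verifies the layout. \code{export_trajectory_csv} writes the
#' interoperable long format with one row per (time, node) pair and
#' columns \code{time, node, x, ve, vi, k}.
#'
#' @param traj A \code{csd_trajectory}.
#' @param path Output file path.
#' @return \code{read_trajectory} returns the restored
#'   \code{csd_trajectory}; the writers return \code{path} invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "csd_trajectory"))
  saveRDS(traj, path, version = 3)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path))
    stop("read_trajectory: file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e)
                    stop("read_trajectory: corrupt or unreadable file: ",
                         conditionMessage(e), call. = FALSE))
  if (!inherits(obj, "csd_trajectory") ||
      !all(c("times", "ve", "vi", "k", "grid", "params") %in% names(obj)))
    stop("read_trajectory: file does not contain a csd_trajectory",
         call. = FALSE)
  if (nrow(obj$ve) != length(obj$times) || ncol(obj$ve) != obj$grid$N)
    stop("read_trajectory: layout mismatch between times, fields and grid",
         call. = FALSE)
  obj
}

#' @rdname write_trajectory
#' @export
export_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "csd_trajectory"))
  n_t <- length(traj$times); n_x <- traj$grid$N
  df <- data.frame(
    time = rep(traj$times, each = n_x),
    node = rep(seq_len(n_x), times = n_t),
    x = rep(traj$grid$x, times = n_t),
    ve = as.vector(t(traj$ve)),
    vi = as.vector(t(traj$vi)),
    k = as.vector(t(traj$k)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
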