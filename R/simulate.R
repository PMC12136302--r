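#' Integration settings
#'
#' @param dt Fixed integration step (model time units, > 0).
#' @param t_final Simulation horizon (>= \code{dt}).
#' @param record_every Record every this-many steps (integer >= 1); the
#'   final step is always recorded.
#' @param seed Reserved for future stochastic extensions; the model is
#'   fully deterministic and the value is carried but unused.
#' @return An object of class \code{"integration_settings"}.
#' @export
integration_settings <- function(dt = 0.01, t_final = 10, record_every = 10,
                                 seed = 0L) {
  if (!is.finite(dt) || dt <= 0)
    stop("integration_settings: 'dt' must be > 0", call. = FALSE)
  if (!is.finite(t_final) || t_final < dt)
    stop("integration_settings: 't_final' must be >= dt", call. = FALSE)
  record_every <- as.integer(record_every)
  if (is.na(record_every) || record_every < 1)
    stop("integration_settings: 'record_every' must be an integer >= 1",
         call. = FALSE)
  structure(list(dt = dt, t_final = t_final, record_every = record_every,
                 seed = as.integer(seed)),
            class = "integration_settings")
}

#' Uniform initial state
#'
#' Builds a spatially uniform resting state. The baseline concentration
#' must lie below the lower potassium threshold of both populations so
#' that the run starts in the normal-activity regime.
#'
#' @param grid A \code{\link{build_grid}} object.
#' @param v0 Baseline potential applied to both populations, or a vector
#'   \code{c(ve0, vi0)}.
#' @param k0 Baseline potassium concentration (>= 0).
#' @param params Optional \code{\link{csd_params}}; when given, \code{k0}
#'   is checked against the \code{k1_star} thresholds.
#' @return A \code{\link{field_state}}.
#' @export
initial_state <- function(grid, v0, k0, params = NULL) {
  stopifnot(inherits(grid, "csd_grid"))
  if (!is.finite(k0) || k0 < 0)
    stop("initial_state: 'k0' must be finite and >= 0", call. = FALSE)
  if (!is.null(params)) {
    stopifnot(inherits(params, "csd_params"))
    if (k0 >= params$transfer_e$k1_star || k0 >= params$transfer_i$k1_star)
      stop("initial_state: 'k0' must be below k1_star of both populations",
           call. = FALSE)
  }
  v0 <- rep_len(v0, 2)
  field_state(ve = rep(v0[1], grid$N), vi = rep(v0[2], grid$N),
              k = rep(k0, grid$N))
}

#' Largest stable step for the explicit diffusion stencil
#'
#' The potassium equation carries \code{delta / tau} times the discrete
#' Laplacian, so the classic explicit bound is
#' \code{tau * hx^2 / (2 * delta)}; \code{\link{simulate_field}} refuses
#' steps above 0.9 times this bound.
#'
#' @param grid A \code{\link{build_grid}} object.
#' @param delta Diffusion constant (>= 0).
#' @param tau Time constant (> 0).
#' @return The step bound; \code{Inf} when \code{delta = 0}.
#' @export
max_stable_dt <- function(grid, delta, tau) {
  stopifnot(inherits(grid, "csd_grid"))
  if (delta < 0 || tau <= 0)
    stop("max_stable_dt: need delta >= 0 and tau > 0", call. = FALSE)
  if (delta == 0) return(Inf)
  tau * grid$hx^2 / (2 * delta)
}

#' Simulate the potassium-coupled neural field
#'
#' Advances the discretized field equations with fixed-step fourth-order
#' Runge-Kutta (method of lines) and records snapshots. Fixed stepping is
#' used deliberately: the firing-rate function is discontinuous in the
#' potassium concentration, which misleads the error estimators of
#' adaptive schemes, and fixed steps make runs bit-reproducible.
#'
#' @param params A \code{\link{csd_params}} object.
#' @param grid A \code{\link{build_grid}} object.
#' @param init A \code{\link{field_state}} (see
#'   \code{\link{initial_state}}).
#' @param settings An \code{\link{integration_settings}} object.
#' @param stimulus A \code{\link{stimulus_params}} object or \code{NULL}.
#' @return An object of class \code{"csd_trajectory"}: list with
#'   \code{times} (recorded instants, starting at 0), \code{ve},
#'   \code{vi}, \code{k} (matrices, rows = recorded times, columns =
#'   nodes), plus the \code{grid}, \code{params}, \code{settings} and
#'   \code{stimulus} that produced it.
#' @export
simulate_field <- function(params, grid, init, settings, stimulus = NULL) {
  stopifnot(inherits(params, "csd_params"), inherits(grid, "csd_grid"),
            inherits(init, "field_state"),
            inherits(settings, "integration_settings"))
  if (length(init$ve) != grid$N)
    stop("simulate_field: initial state does not match grid", call. = FALSE)
  dt <- settings$dt
  bound <- max_stable_dt(grid, params$coupling$delta, params$coupling$tau)
  if (dt > 0.9 * bound)
    stop(sprintf(paste0("simulate_field: dt = %g exceeds 0.9 * stability ",
                        "bound %g; reduce dt or diffusion"), dt, bound),
         call. = FALSE)

  n_steps <- max(1L, as.integer(round(settings$t_final / dt)))
  every <- settings$record_every
  W <- interaction_matrix(grid)

  ve <- init$ve; vi <- init$vi; k <- init$k
  rec_idx <- unique(c(seq(0L, n_steps - 1L, by = every), n_steps))
  n_rec <- length(rec_idx)
  ve_m <- matrix(NA_real_, n_rec, grid$N)
  vi_m <- matrix(NA_real_, n_rec, grid$N)
  k_m <- matrix(NA_real_, n_rec, grid$N)
  times <- numeric(n_rec)
  ri <- 1L

  deriv <- function(ve, vi, k, t) {
    rhs_raw(ve, vi, k, t, params, grid, stimulus, W)
  }

  for (i in 0:(n_steps - 1L)) {
    t <- i * dt
    if (i == rec_idx[ri]) {
      ve_m[ri, ] <- ve; vi_m[ri, ] <- vi; k_m[ri, ] <- k
      times[ri] <- t
      ri <- ri + 1L
    }
    d1 <- deriv(ve, vi, k, t)
    d2 <- deriv(ve + dt / 2 * d1$dve, vi + dt / 2 * d1$dvi,
                k + dt / 2 * d1$dk, t + dt / 2)
    d3 <- deriv(ve + dt / 2 * d2$dve, vi + dt / 2 * d2$dvi,
                k + dt / 2 * d2$dk, t + dt / 2)
    d4 <- deriv(ve + dt * d3$dve, vi + dt * d3$dvi,
                k + dt * d3$dk, t + dt)
    ve <- ve + dt / 6 * (d1$dve + 2 * d2$dve + 2 * d3$dve + d4$dve)
    vi <- vi + dt / 6 * (d1$dvi + 2 * d2$dvi + 2 * d3$dvi + d4$dvi)
    k <- k + dt / 6 * (d1$dk + 2 * d2$dk + 2 * d3$dk + d4$dk)
    if (any(!is.finite(ve)) || any(!is.finite(vi)) || any(!is.finite(k)))
      stop(sprintf("simulate_field: non-finite state at t = %g", (i + 1) * dt),
           call. = FALSE)
  }
  ve_m[ri, ] <- ve; vi_m[ri, ] <- vi; k_m[ri, ] <- k
  times[ri] <- n_steps * dt

  structure(list(times = times, ve = ve_m, vi = vi_m, k = k_m,
                 grid = grid, params = params, settings = settings,
                 stimulus = stimulus),
            class = "csd_trajectory")
}

#' @export
print.csd_trajectory <- function(x, ...) {
  cat(sprintf(paste0("CSD field trajectory: %d snapshots over t = [0, %g], ",
                     "N = %d nodes\n"),
              length(x$times), max(x$times), x$grid$N))
  cat(sprintf("  final ve range: [%.3f, %.3f], final k range: [%.3f, %.3f]\n",
              min(x$ve[nrow(x$ve), ]), max(x$ve[nrow(x$ve), ]),
              min(x$k[nrow(x$k), ]), max(x$k[nrow(x$k), ])))
  invisible(x)
}

#' @export
summary.csd_trajectory <- function(object, ...) {
  tot_k <- rowSums(object$k) * object$grid$hx
  out <- list(n_snapshots = length(object$times),
              t_final = max(object$times),
              N = object$grid$N,
              ve_range = range(object$ve),
              k_range = range(object$k),
              total_k_initial = tot_k[1],
              total_k_final = tot_k[length(tot_k)])
  class(out) <- "summary.csd_trajectory"
  out
}

#' @export
print.summary.csd_trajectory <- function(x, ...) {
  cat(sprintf("CSD trajectory: %d snapshots, t in [0, %g], N = %d\n",
              x$n_snapshots, x$t_final, x$N))
  cat(sprintf("  ve in [%.3f, %.3f]; k in [%.3f, %.3f]\n",
              x$ve_range[1], x$ve_range[2], x$k_range[1], x$k_range[2]))
  cat(sprintf("  total K+ content: %.4f -> %.4f\n",
              x$total_k_initial, x$total_k_final))
  invisible(x)
}
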