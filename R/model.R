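#' Full model parameter record
#'
#' Bundles every parameter group of the potassium-coupled neural field:
#' per-population firing-rate transfer parameters, the potassium drive,
#' the potassium production, and the synaptic coupling weights.
#'
#' @param transfer_e,transfer_i \code{\link{transfer_params}} for the
#'   excitatory and inhibitory populations.
#' @param drive A \code{\link{potassium_drive_params}} object.
#' @param production A \code{\link{potassium_production_params}} object;
#'   \code{v_star} must exceed the half-response voltage of both
#'   populations for the reference rates to sit on the upper part of the
#'   sigmoid.
#' @param coupling A \code{\link{coupling_params}} object.
#' @return An object of class \code{"csd_params"}. The derived reference
#'   rates \code{s_star_e} and \code{s_star_i} are recomputed by
#'   \code{\link{reference_rate}} on construction and whenever a field is
#'   replaced via \code{\link{update_params}}; they are never cached
#'   stale.
#' @export
csd_params <- function(transfer_e, transfer_i, drive, production, coupling) {
  stopifnot(inherits(transfer_e, "transfer_params"),
            inherits(transfer_i, "transfer_params"),
            inherits(drive, "potassium_drive_params"),
            inherits(production, "potassium_production_params"),
            inherits(coupling, "coupling_params"))
  if (production$v_star <= transfer_e$h || production$v_star <= transfer_i$h)
    stop("csd_params: 'v_star' must exceed the half-response voltage of ",
         "both populations", call. = FALSE)
  obj <- structure(list(transfer_e = transfer_e, transfer_i = transfer_i,
                        drive = drive, production = production,
                        coupling = coupling),
                   class = "csd_params")
  obj$s_star_e <- reference_rate(transfer_e, production)
  obj$s_star_i <- reference_rate(transfer_i, production)
  obj
}

#' Update fields of a parameter record
#'
#' Replaces named scalar parameters anywhere in the nested record and
#' revalidates; derived reference rates are recomputed. Names address the
#' flat reference-configuration keys (see \code{\link{reference_config}}),
#' e.g. \code{c_ei}, \code{kv_star}, \code{beta_e}.
#'
#' @param params A \code{\link{csd_params}} object.
#' @param ... Named scalar replacements.
#' @return A new \code{csd_params} object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "csd_params"))
  repl <- list(...)
  if (!length(repl)) return(params)
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("update_params: replacements must be named", call. = FALSE)
  flat <- params_to_list(params)
  for (nm in names(repl)) {
    if (!nm %in% names(flat))
      stop(sprintf("update_params: unknown parameter '%s'", nm),
           call. = FALSE)
    flat[[nm]] <- repl[[nm]]
  }
  params_from_list(flat)
}

# flatten to the config key set
params_to_list <- function(params) {
  te <- params$transfer_e; ti <- params$transfer_i
  dr <- params$drive; pr <- params$production; cp <- params$coupling
  list(beta_e = te$beta, h_e = te$h,
       beta_i = ti$beta, h_i = ti$h,
       k1_star = te$k1_star, k2_star = te$k2_star,
       beta_ve = dr$beta_ve, beta_vi = dr$beta_vi, kv_star = dr$kv_star,
       a = pr$a, b = pr$b, c = pr$c, v_star = pr$v_star,
       c_ee = cp$c_ee, c_ei = cp$c_ei, c_ie = cp$c_ie, c_ii = cp$c_ii,
       c1 = cp$c1, c2 = cp$c2, tau = cp$tau, delta = cp$delta)
}

params_from_list <- function(x) {
  csd_params(
    transfer_e = transfer_params(x$beta_e, x$h_e, x$k1_star, x$k2_star),
    transfer_i = transfer_params(x$beta_i, x$h_i, x$k1_star, x$k2_star),
    drive = potassium_drive_params(x$beta_ve, x$beta_vi, x$kv_star),
    production = potassium_production_params(x$a, x$b, x$c, x$v_star),
    coupling = coupling_params(x$c_ee, x$c_ei, x$c_ie, x$c_ii,
                               x$c1, x$c2, x$tau, x$delta))
}

#' @export
print.csd_params <- function(x, ...) {
  cp <- x$coupling
  cat("Potassium-coupled neural field parameters\n")
  cat(sprintf("  coupling: c_ee=%g c_ei=%g c_ie=%g c_ii=%g c1=%g c2=%g\n",
              cp$c_ee, cp$c_ei, cp$c_ie, cp$c_ii, cp$c1, cp$c2))
  cat(sprintf("  tau=%g delta=%g kv_star=%g k1_star=%g k2_star=%g\n",
              cp$tau, cp$delta, x$drive$kv_star,
              x$transfer_e$k1_star, x$transfer_e$k2_star))
  cat(sprintf("  reference rates: s_star_e=%.4f s_star_i=%.4f\n",
              x$s_star_e, x$s_star_i))
  invisible(x)
}

#' Right-hand side of the discretized field equations
#'
#' Evaluates the time derivatives of the excitatory potential, inhibitory
#' potential and potassium concentration at every node:
#' \deqn{\tau \dot v_e = -v_e + c_{ee} S_e - c_{ei} S_i + g_v(v_e, k)}
#' \deqn{\tau \dot v_i = -v_i + c_{ie} S_e - c_{ii} S_i + g_v(v_i, k)}
#' \deqn{\tau \dot k = \delta \partial_x^2 k + c_1 g_k(s_e) + c_2 g_k(s_i) + I}
#' where \eqn{S_e, S_i} are the nonlocal kernel interactions of the
#' population rates and \eqn{g_k} is evaluated against the per-population
#' reference rate. Returned derivatives are already divided by \eqn{\tau}.
#'
#' @param state A \code{\link{field_state}}.
#' @param t Time (model units), used by the stimulus window.
#' @param params A \code{\link{csd_params}} object.
#' @param grid A \code{\link{build_grid}} object.
#' @param stimulus A \code{\link{stimulus_params}} object or \code{NULL}
#'   for no input.
#' @param W Optional precomputed \code{\link{interaction_matrix}}.
#' @return A list with components \code{dve}, \code{dvi}, \code{dk}.
#' @export
field_rhs <- function(state, t, params, grid, stimulus = NULL, W = NULL) {
  stopifnot(inherits(state, "field_state"), inherits(params, "csd_params"),
            inherits(grid, "csd_grid"))
  if (length(state$ve) != grid$N)
    stop("field_rhs: state length does not match grid", call. = FALSE)
  if (is.null(W)) W <- interaction_matrix(grid)
  rhs_raw(state$ve, state$vi, state$k, t, params, grid, stimulus, W)
}

# unvalidated rhs core used by the integrator; non-finite intermediate
# values must propagate so divergence is detected at the step level
rhs_raw <- function(ve, vi, k, t, params, grid, stimulus, W) {
  cp <- params$coupling; dr <- params$drive; pr <- params$production
  sig_e <- .sigmoid(params$transfer_e$beta * (ve - params$transfer_e$h))
  sig_i <- .sigmoid(params$transfer_i$beta * (vi - params$transfer_i$h))
  low <- k < params$transfer_e$k1_star
  blk <- k > params$transfer_e$k2_star
  se <- ifelse(blk, 0, ifelse(low, 0.5 * sig_e, sig_e))
  low_i <- k < params$transfer_i$k1_star
  blk_i <- k > params$transfer_i$k2_star
  si <- ifelse(blk_i, 0, ifelse(low_i, 0.5 * sig_i, sig_i))
  Se <- drop(W %*% se)
  Si <- drop(W %*% si)
  gv_e <- .sigmoid(dr$beta_ve * (k - dr$kv_star))
  gv_i <- .sigmoid(dr$beta_vi * (k - dr$kv_star))
  I <- if (is.null(stimulus)) 0 else stimulus_profile(grid, t, stimulus)

  # no-flux Laplacian, inlined
  n <- grid$N
  lap <- numeric(n)
  lap[2:(n - 1)] <- (k[1:(n - 2)] - 2 * k[2:(n - 1)] + k[3:n]) / grid$hx^2
  lap[1] <- (k[2] - k[1]) / grid$hx^2
  lap[n] <- (k[n - 1] - k[n]) / grid$hx^2

  dve <- (-ve + cp$c_ee * Se - cp$c_ei * Si + gv_e) / cp$tau
  dvi <- (-vi + cp$c_ie * Se - cp$c_ii * Si + gv_i) / cp$tau
  dk <- (cp$delta * lap +
           cp$c1 * pr$a * cosh(pr$b * (se - pr$c * params$s_star_e)) +
           cp$c2 * pr$a * cosh(pr$b * (si - pr$c * params$s_star_i)) +
           I) / cp$tau
  list(dve = dve, dvi = dvi, dk = dk)
}
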