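#' Transfer-function parameter sets
#'
#' Constructors for the three parameter groups entering the nonlinear
#' transfer functions of the model: the per-population firing-rate
#' parameters, the potassium-to-potential drive parameters, and the
#' rate-to-potassium production parameters.
#'
#' @param beta Sharpness of the firing-rate sigmoid (dimensionless, > 0).
#' @param h Half-response voltage of the sigmoid (model voltage units).
#' @param k1_star Lower potassium threshold separating the normal-activity
#'   regime from the hyperactivity regime (model concentration units, > 0).
#' @param k2_star Upper potassium threshold above which the population
#'   enters depolarization block (> \code{k1_star}).
#'
#' @return \code{transfer_params} returns an object of class
#'   \code{"transfer_params"}; the other constructors return objects of
#'   class \code{"potassium_drive_params"} and
#'   \code{"potassium_production_params"}.
#'
#' @details The firing-rate function has three potassium regimes: for
#'   \code{k < k1_star} a sigmoid saturating at 1/2 (normal activity), for
#'   \code{k1_star <= k <= k2_star} a sigmoid saturating at 1
#'   (hyperactivity), and for \code{k > k2_star} the rate is 0
#'   (depolarization block).
#'
#' @examples
#' pe <- transfer_params(beta = 2, h = -5.5, k1_star = 1.25, k2_star = 1.55)
#' firing_rate(v = -5.5, k = 0.5, pe)   # half-maximum of the low branch
#' @export
transfer_params <- function(beta, h, k1_star, k2_star) {
  stopifnot(is.numeric(beta), is.numeric(h), is.numeric(k1_star),
            is.numeric(k2_star))
  if (!is.finite(beta) || beta <= 0)
    stop("transfer_params: 'beta' must be finite and > 0", call. = FALSE)
  if (!is.finite(h))
    stop("transfer_params: 'h' must be finite", call. = FALSE)
  if (!is.finite(k1_star) || k1_star <= 0)
    stop("transfer_params: 'k1_star' must be finite and > 0", call. = FALSE)
  if (!is.finite(k2_star) || k2_star <= k1_star)
    stop("transfer_params: 'k2_star' must be > k1_star", call. = FALSE)
  structure(list(beta = beta, h = h, k1_star = k1_star, k2_star = k2_star),
            class = "transfer_params")
}

#' @rdname transfer_params
#' @param beta_ve,beta_vi Sharpness of the potassium drive acting on the
#'   excitatory and inhibitory population potentials (> 0).
#' @param kv_star Potassium threshold of the drive (model concentration
#'   units); the drive is 1/2 at \code{k = kv_star}.
#' @export
potassium_drive_params <- function(beta_ve, beta_vi, kv_star) {
  if (!is.finite(beta_ve) || beta_ve <= 0)
    stop("potassium_drive_params: 'beta_ve' must be > 0", call. = FALSE)
  if (!is.finite(beta_vi) || beta_vi <= 0)
    stop("potassium_drive_params: 'beta_vi' must be > 0", call. = FALSE)
  if (!is.finite(kv_star))
    stop("potassium_drive_params: 'kv_star' must be finite", call. = FALSE)
  structure(list(beta_ve = beta_ve, beta_vi = beta_vi, kv_star = kv_star),
            class = "potassium_drive_params")
}

#' @rdname transfer_params
#' @param a Baseline production scale (> 0); the minimum of the production
#'   function, so potassium production is strictly positive everywhere.
#' @param b Production sharpness (>= 0); amplifies deviations of the firing
#'   rate from its reference level.
#' @param c Reference-rate multiplier (>= 0); the production minimum sits
#'   at rate \code{c * s_star}.
#' @param v_star Reference voltage at which the reference rate
#'   \code{s_star = s(v_star, k1_star)} is evaluated; must exceed \code{h}
#'   of the corresponding population.
#' @export
potassium_production_params <- function(a, b, c, v_star) {
  if (!is.finite(a) || a <= 0)
    stop("potassium_production_params: 'a' must be > 0", call. = FALSE)
  if (!is.finite(b) || b < 0)
    stop("potassium_production_params: 'b' must be >= 0", call. = FALSE)
  if (!is.finite(c) || c < 0)
    stop("potassium_production_params: 'c' must be >= 0", call. = FALSE)
  if (!is.finite(v_star))
    stop("potassium_production_params: 'v_star' must be finite", call. = FALSE)
  structure(list(a = a, b = b, c = c, v_star = v_star),
            class = "potassium_production_params")
}

# sigmoid with overflow guard; the clip at |x| = 700 changes values by
# less than 1e-300, far below any tolerance used in the package
.sigmoid <- function(x) {
  x <- pmin(pmax(x, -700), 700)
  1 / (1 + exp(-x))
}

#' Three-regime firing-rate transfer function
#'
#' Maps average membrane potential and extracellular potassium
#' concentration to a population firing rate in \[0, 1\]. The potassium
#' concentration selects one of three regimes: below \code{k1_star} a
#' sigmoid saturating at 1/2 (normal activity); between \code{k1_star} and
#' \code{k2_star} (inclusive) a sigmoid saturating at 1 (hyperactivity);
#' above \code{k2_star} the rate is identically 0 (depolarization block).
#'
#' @param v Average membrane potential (scalar or vector).
#' @param k Extracellular potassium concentration (scalar or vector,
#'   recycled against \code{v}).
#' @param params A \code{\link{transfer_params}} object.
#' @return Firing rate(s) in \[0, 1\], same length as the longer of
#'   \code{v} and \code{k}.
#' @export
firing_rate <- function(v, k, params) {
  stopifnot(inherits(params, "transfer_params"))
  if (any(!is.finite(v)) || any(!is.finite(k)))
    stop("firing_rate: non-finite input", call. = FALSE)
  n <- max(length(v), length(k))
  v <- rep_len(v, n); k <- rep_len(k, n)
  sig <- .sigmoid(params$beta * (v - params$h))
  out <- numeric(n)
  low  <- k < params$k1_star
  mid  <- k >= params$k1_star & k <= params$k2_star
  out[low] <- 0.5 * sig[low]
  out[mid] <- sig[mid]
  out  # k > k2_star stays 0
}

#' Potassium-to-potential drive
#'
#' Sigmoidal drive of the extracellular potassium concentration on a
#' population potential. The potential argument is accepted for signature
#' parity with the field equations but does not enter the formula; the
#' drive depends on the concentration alone.
#'
#' @param v Average membrane potential (ignored by the formula).
#' @param k Extracellular potassium concentration.
#' @param beta_v Sharpness (> 0).
#' @param kv_star Threshold concentration; the drive is 1/2 there.
#' @return Drive value(s) in (0, 1), strictly increasing in \code{k}.
#' @export
potassium_drive <- function(v, k, beta_v, kv_star) {
  if (any(!is.finite(k)))
    stop("potassium_drive: non-finite input", call. = FALSE)
  if (!is.finite(beta_v) || beta_v <= 0)
    stop("potassium_drive: 'beta_v' must be > 0", call. = FALSE)
  .sigmoid(beta_v * (k - kv_star))
}

#' Firing-rate-to-potassium production
#'
#' Potassium production generated by population activity,
#' \code{a * cosh(b * (s - c * s_star))}. The minimum value \code{a} is
#' attained where the rate equals the reference level \code{c * s_star};
#' deviations in either direction are amplified hyperbolically.
#'
#' @param s Firing rate(s).
#' @param s_star Reference rate, normally
#'   \code{firing_rate(v_star, k1_star, params)} for the population.
#' @param a,b,c Production parameters; see
#'   \code{\link{potassium_production_params}}.
#' @return Production value(s), always >= \code{a}.
#' @export
rate_to_potassium <- function(s, s_star, a, b, c) {
  if (any(!is.finite(s)) || any(!is.finite(s_star)))
    stop("rate_to_potassium: non-finite input", call. = FALSE)
  if (!is.finite(a) || a <= 0) stop("rate_to_potassium: 'a' must be > 0",
                                    call. = FALSE)
  if (b < 0 || c < 0) stop("rate_to_potassium: 'b' and 'c' must be >= 0",
                           call. = FALSE)
  a * cosh(b * (s - c * s_star))
}

#' Reference rate for the production function
#'
#' Evaluates \code{s_star = s(v_star, k1_star)} for a population. The
#' reference sits on the hyperactivity branch because \code{k = k1_star}
#' belongs to the middle regime.
#'
#' @param tp A \code{\link{transfer_params}} object.
#' @param prod A \code{\link{potassium_production_params}} object.
#' @return The scalar reference rate.
#' @export
reference_rate <- function(tp, prod) {
  stopifnot(inherits(tp, "transfer_params"),
            inherits(prod, "potassium_production_params"))
  if (prod$v_star <= tp$h)
    stop("reference_rate: 'v_star' must exceed 'h'", call. = FALSE)
  firing_rate(prod$v_star, tp$k1_star, tp)
}

#' Gaussian connectivity kernel
#'
#' Synaptic footprint on the 1D propagation axis,
#' \code{w(d) = exp(-d^2) / 2}, evaluated at a signed distance in grid
#' coordinates. Even in \code{d} and maximal (1/2) at \code{d = 0}.
#'
#' @param d Signed distance(s) between two axis positions.
#' @return Kernel weight(s) in (0, 0.5\].
#' @export
connectivity_kernel <- function(d) {
  if (any(!is.finite(d)))
    stop("connectivity_kernel: non-finite input", call. = FALSE)
  0.5 * exp(-d^2)
}
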