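#' Build the 1D propagation axis
#'
#' Constructs the equidistant grid of neural-field units on the
#' propagation axis Q of half-length \code{Lx}: spacing
#' \code{hx = 2 * Lx / (N - 1)} and coordinates \code{-Lx + j * hx}.
#' With odd \code{N} the center node sits exactly at 0, which is where
#' the triggering stimulus is applied and from where propagation
#' distances are measured.
#'
#' @param Lx Half-length of the axis (grid-coordinate units, > 0).
#' @param N Number of nodes (integer >= 2; odd in all reference
#'   configurations).
#' @return An object of class \code{"csd_grid"} with fields \code{Lx},
#'   \code{N}, \code{hx} and the coordinate vector \code{x}.
#' @examples
#' g <- build_grid(Lx = 1, N = 3)
#' g$x   # -1 0 1
#' @export
build_grid <- function(Lx, N) {
  if (!is.finite(Lx) || Lx <= 0)
    stop("build_grid: 'Lx' must be finite and > 0", call. = FALSE)
  N <- as.integer(N)
  if (is.na(N) || N < 2)
    stop("build_grid: 'N' must be an integer >= 2", call. = FALSE)
  hx <- 2 * Lx / (N - 1)
  x <- -Lx + hx * (0:(N - 1))
  structure(list(Lx = Lx, N = N, hx = hx, x = x), class = "csd_grid")
}

#' @export
print.csd_grid <- function(x, ...) {
  cat(sprintf("1D propagation axis: N = %d nodes on [-%g, %g], hx = %g\n",
              x$N, x$Lx, x$Lx, x$hx))
  invisible(x)
}

# center node index (1-based); odd N puts it exactly at x = 0
grid_center <- function(grid) (grid$N + 1L) %/% 2L

#' Synaptic coupling and potassium transport parameters
#'
#' @param c_ee,c_ei,c_ie,c_ii Synaptic connection weights (>= 0). First
#'   subscript = target population, second = source: \code{c_ei}
#'   multiplies the inhibitory interaction in the excitatory equation.
#' @param c1,c2 Contribution weights of excitatory and inhibitory activity
#'   to extracellular potassium production (>= 0).
#' @param tau Relaxation time constant shared by all three field
#'   equations (model time units, > 0).
#' @param delta Potassium diffusion constant (>= 0).
#' @return An object of class \code{"coupling_params"}.
#' @export
coupling_params <- function(c_ee = 1, c_ei = 15, c_ie = 1, c_ii = 15,
                            c1 = 15, c2 = 15, tau = 0.15, delta = 1) {
  w <- c(c_ee = c_ee, c_ei = c_ei, c_ie = c_ie, c_ii = c_ii,
         c1 = c1, c2 = c2)
  if (any(!is.finite(w)) || any(w < 0))
    stop("coupling_params: weights must be finite and >= 0", call. = FALSE)
  if (!is.finite(tau) || tau <= 0)
    stop("coupling_params: 'tau' must be > 0", call. = FALSE)
  if (!is.finite(delta) || delta < 0)
    stop("coupling_params: 'delta' must be >= 0", call. = FALSE)
  structure(list(c_ee = c_ee, c_ei = c_ei, c_ie = c_ie, c_ii = c_ii,
                 c1 = c1, c2 = c2, tau = tau, delta = delta),
            class = "coupling_params")
}

#' Focal stimulus parameters
#'
#' A Gaussian bump in space and a rectangular pulse in time added to the
#' potassium equation, emulating the focal KCl puff used to trigger CSD.
#'
#' @param amplitude Peak input rate (concentration per model time, >= 0).
#' @param center Bump center (grid coordinate).
#' @param width Gaussian width parameter (> 0).
#' @param onset Pulse start time (>= 0).
#' @param duration Pulse duration (>= 0).
#' @return An object of class \code{"stimulus_params"}.
#' @export
stimulus_params <- function(amplitude = 2, center = 0, width = 1.5,
                            onset = 0, duration = 0.3) {
  if (!is.finite(amplitude) || amplitude < 0)
    stop("stimulus_params: 'amplitude' must be >= 0", call. = FALSE)
  if (!is.finite(width) || width <= 0)
    stop("stimulus_params: 'width' must be > 0", call. = FALSE)
  if (!is.finite(onset) || onset < 0)
    stop("stimulus_params: 'onset' must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration < 0)
    stop("stimulus_params: 'duration' must be >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, center = center, width = width,
                 onset = onset, duration = duration),
            class = "stimulus_params")
}

#' Field state at one instant
#'
#' Bundles the per-node excitatory potential, inhibitory potential and
#' extracellular potassium concentration.
#'
#' @param ve,vi Numeric vectors of population potentials, length N.
#' @param k Numeric vector of potassium concentrations, length N,
#'   non-negative.
#' @return An object of class \code{"field_state"}.
#' @export
field_state <- function(ve, vi, k) {
  n <- length(ve)
  if (length(vi) != n || length(k) != n)
    stop("field_state: 've', 'vi' and 'k' must have equal length",
         call. = FALSE)
  if (any(!is.finite(ve)) || any(!is.finite(vi)) || any(!is.finite(k)))
    stop("field_state: non-finite entries", call. = FALSE)
  structure(list(ve = ve, vi = vi, k = k), class = "field_state")
}

#' Dense interaction matrix for the nonlocal coupling
#'
#' Precomputes the rectangle-rule quadrature of the Gaussian connectivity
#' kernel over the truncated axis: \code{W[j, m] = hx * w(x_j - x_m)}.
#' Multiplying a rate vector by \code{W} evaluates the interaction
#' integral at every node. Kernel mass lost by truncation at the axis
#' ends is accepted (no periodic wrap).
#'
#' @param grid A \code{\link{build_grid}} object.
#' @return An N x N matrix.
#' @export
interaction_matrix <- function(grid) {
  stopifnot(inherits(grid, "csd_grid"))
  D <- outer(grid$x, grid$x, "-")
  grid$hx * connectivity_kernel(D)
}

#' Nonlocal interaction of a rate field
#'
#' Rectangle-rule discretization of the convolution of per-node firing
#' rates with the Gaussian connectivity kernel. Used identically for the
#' excitatory and the inhibitory interaction term.
#'
#' @param rates Per-node firing rates, length N.
#' @param grid A \code{\link{build_grid}} object.
#' @param W Optional precomputed \code{\link{interaction_matrix}}; pass it
#'   when calling repeatedly on the same grid.
#' @return Per-node interaction values, length N.
#' @export
interaction <- function(rates, grid, W = NULL) {
  stopifnot(inherits(grid, "csd_grid"))
  if (length(rates) != grid$N)
    stop("interaction: 'rates' must have length N", call. = FALSE)
  if (is.null(W)) W <- interaction_matrix(grid)
  drop(W %*% rates)
}

#' Discrete Laplacian with no-flux boundaries
#'
#' Central second difference on interior nodes with a finite-volume
#' no-flux (homogeneous Neumann) closure at both ends: the flux through
#' the domain boundary is zero, so the node-sum of the operator vanishes
#' identically and diffusion conserves the total potassium content of
#' the axis.
#'
#' @param k Per-node concentrations, length N >= 3.
#' @param grid A \code{\link{build_grid}} object.
#' @return Per-node second-derivative estimates, length N.
#' @export
laplacian <- function(k, grid) {
  stopifnot(inherits(grid, "csd_grid"))
  n <- grid$N
  if (n < 3)
    stop("laplacian: grid must have at least 3 nodes", call. = FALSE)
  if (length(k) != n)
    stop("laplacian: 'k' must have length N", call. = FALSE)
  out <- numeric(n)
  out[2:(n - 1)] <- (k[1:(n - 2)] - 2 * k[2:(n - 1)] + k[3:n]) / grid$hx^2
  # zero-flux boundary faces: the node-sum telescopes to exactly 0
  out[1] <- (k[2] - k[1]) / grid$hx^2
  out[n] <- (k[n - 1] - k[n]) / grid$hx^2
  out
}

#' Stimulus profile at a given time
#'
#' @param grid A \code{\link{build_grid}} object.
#' @param t Time (model units).
#' @param params A \code{\link{stimulus_params}} object.
#' @return Per-node input values; all zero outside the pulse window
#'   \code{[onset, onset + duration)}.
#' @export
stimulus_profile <- function(grid, t, params) {
  stopifnot(inherits(grid, "csd_grid"), inherits(params, "stimulus_params"))
  if (t >= params$onset && t < params$onset + params$duration)
    params$amplitude * exp(-((grid$x - params$center) / params$width)^2)
  else
    numeric(grid$N)
}
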