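#' Orientation grid, stimulus and gain of the ring model
#'
#' `ring_grid()` returns the `n` uniformly spaced orientation preferences
#' on the half-open interval \eqn{[-\pi/2, \pi/2)} used by the rectangle
#' rule; `bimodal_input()` evaluates the stationary bimodal stimulus
#' \deqn{I(x) = -I_0 \cos(4x) + I_a \sin(2x),}
#' which peaks at the two orthogonal orientations \eqn{\pm\pi/4} with
#' heights \eqn{I_R = I_0 + I_a} (right) and \eqn{I_L = I_0 - I_a}
#' (left); `gain_fun()` evaluates the firing-rate gain, either the
#' Heaviside step \eqn{H(u-\kappa)} (with \eqn{H(0)=1}) in the
#' `gamma = Inf` limit or the logistic sigmoid
#' \eqn{1/(1+e^{-\gamma(u-\kappa)})}.
#'
#' @param n number of grid points.
#' @param x orientation angle(s) in \eqn{[-\pi/2, \pi/2)}.
#' @param I0,Ia symmetric and asymmetric stimulus amplitudes.
#' @param u synaptic input value(s).
#' @param kappa firing threshold.
#' @param gamma sigmoid gain (`Inf` for Heaviside).
#' @return Numeric vector.
#' @examples
#' bimodal_input(pi / 4, I0 = 0.9, Ia = 0.02)  # I_R = 0.92
#' @export
bimodal_input <- function(x, I0, Ia = 0) {
  -I0 * cos(4 * x) + Ia * sin(2 * x)
}

#' @rdname bimodal_input
#' @export
ring_grid <- function(n) {
  seq(-pi / 2, pi / 2, length.out = n + 1)[seq_len(n)]
}

#' @rdname bimodal_input
#' @export
gain_fun <- function(u, kappa, gamma = Inf) {
  if (is.infinite(gamma)) as.numeric(u >= kappa)
  else 1 / (1 + exp(-gamma * (u - kappa)))
}

#' Recurrent synaptic drive of the ring model
#'
#' Evaluates the convolution \eqn{w * (q f(u))} with the cosine kernel
#' \eqn{w(x-y) = \cos(2(x-y))} over the periodic orientation domain,
#' using the separability
#' \eqn{\cos(2(x-y)) = \cos 2x \cos 2y + \sin 2x \sin 2y}: two inner
#' products against the grid replace the full quadrature, so the cost is
#' O(n) per evaluation. The quadrature weight is the rectangle-rule
#' weight \eqn{\pi / n}.
#'
#' @param u synaptic input on the grid.
#' @param q synaptic resource fraction on the grid (same length).
#' @param kappa,gamma gain parameters passed to [gain_fun()].
#' @param x grid returned by [ring_grid()]; defaults to the grid implied
#'   by `length(u)`.
#' @return Numeric vector: the drive at every grid point.
#' @export
recurrent_drive <- function(u, q, kappa, gamma = Inf, x = NULL) {
  if (length(u) != length(q))
    stop("`u` and `q` have different lengths: corrupted field state")
  n <- length(u)
  if (is.null(x)) x <- ring_grid(n)
  f <- gain_fun(u, kappa, gamma)
  qf <- q * f
  dx <- pi / n
  A <- sum(cos(2 * x) * qf) * dx
  B <- sum(sin(2 * x) * qf) * dx
  A * cos(2 * x) + B * sin(2 * x)
}

#' Spatially correlated noise increments on the ring
#'
#' Draws Euler--Maruyama noise increments
#' \eqn{\xi(x)\sqrt{dt}} with
#' \eqn{\xi(x) = \sqrt{\epsilon s}\,(\eta_1 \cos x + \eta_2 \sin x)},
#' \eqn{\eta_{1,2}} iid standard normal per step, which realizes the
#' spatiotemporal covariance
#' \eqn{\langle\xi(x,t)\xi(y,s)\rangle = \epsilon s \cos(x-y)\delta(t-s)}.
#' The rank-2 construction is exact for the cosine correlation profile;
#' note the profile has period \eqn{2\pi} while the domain has length
#' \eqn{\pi}, so the two domain endpoints are anti-correlated.
#'
#' @param params a [ring_params()] object.
#' @param n_steps number of increments to draw.
#' @return An `n_steps` x `n_grid` matrix of increments (already scaled
#'   by \eqn{\sqrt{dt}}).
#' @export
sample_noise <- function(params, n_steps) {
  stopifnot(inherits(params, "ring_params"))
  x <- ring_grid(params$n_grid)
  amp <- sqrt(params$eps * params$noise_corr_scale * params$dt)
  if (amp == 0) return(matrix(0, n_steps, params$n_grid))
  eta <- matrix(stats::rnorm(2 * n_steps), n_steps, 2)
  amp * (eta[, 1, drop = FALSE] %*% t(cos(x)) +
         eta[, 2, drop = FALSE] %*% t(sin(x)))
}
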