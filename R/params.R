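#' Parameter sets for the competitive network models
#'
#' Constructors for validated parameter lists used by the simulators.
#' All times are in model units; one model unit corresponds to
#' `time_unit_ms` milliseconds (10 ms by default, the excitatory synaptic
#' timescale), so a dominance time of 70 model units is 0.70 s.
#'
#' `ring_params()` parameterizes the stochastic ring neural field on the
#' orientation domain \eqn{x \in [-\pi/2, \pi/2)}: synaptic drive u(x,t)
#' with cosine connectivity \eqn{\cos(2(x-y))}, short-term synaptic
#' depression q(x,t) (depletion rate `beta`, recovery timescale `tau`),
#' a bimodal stimulus with mean amplitude `I0` and asymmetry `Ia`, and
#' spatially correlated noise of variance `eps` per unit time with
#' correlation \eqn{\epsilon \cdot \mathrm{scale} \cdot \cos(x-y)}.
#'
#' `reduced_params()` parameterizes the space-free two-population
#' mutual-inhibition network (inputs `IR`, `IL`, independent white noise
#' of variance `eps` on each activity variable), and
#' `tristable_params()` the three-population analog with a common input
#' strength `I`.
#'
#' @param kappa firing threshold of the gain function (dimensionless).
#' @param beta depression depletion rate (dimensionless, >= 0); `beta = 0`
#'   disables depression.
#' @param tau depression recovery timescale (model units); physiological
#'   range 20--80, default 50 (0.5 s).
#' @param tau_m membrane/synaptic timescale (model units, default 1).
#' @param I0 symmetric amplitude of the bimodal input.
#' @param Ia asymmetry amplitude; the right peak receives
#'   \eqn{I_R = I_0 + I_a}, the left \eqn{I_L = I_0 - I_a}.
#' @param eps noise variance per unit time (>= 0).
#' @param gamma sigmoid gain; `Inf` (default) selects the Heaviside limit
#'   with the convention \eqn{H(0) = 1}.
#' @param n_grid number of uniformly spaced grid points on
#'   \eqn{[-\pi/2, \pi/2)} (>= 8, <= 4096).
#' @param dt Euler--Maruyama timestep (model units).
#' @param t_total simulated duration (model units).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param noise_corr_scale coefficient on the cosine spatial noise
#'   correlation: the noise covariance is
#'   `eps * noise_corr_scale * cos(x - y)`. Default 1; `pi` selects the
#'   alternative normalization.
#' @param time_unit_ms physical milliseconds per model time unit.
#' @param IR,IL input strengths to the right/left populations of the
#'   reduced network.
#' @param I common input strength of the tristable network.
#'
#' @return A validated parameter list of class `"ring_params"`,
#'   `"reduced_params"` or `"tristable_params"` (all inheriting from
#'   `"multistable_params"`).
#'
#' @examples
#' p <- ring_params(I0 = 0.84, beta = 1, t_total = 200)
#' p$I0
#' @export
ring_params <- function(kappa = 0.5, beta = 1, tau = 50, tau_m = 1,
                        I0 = 0.84, Ia = 0, eps = 0, gamma = Inf,
                        n_grid = 512, dt = 1e-3, t_total = 1000,
                        seed = NULL, noise_corr_scale = 1,
                        time_unit_ms = 10) {
  p <- list(kappa = kappa, beta = beta, tau = tau, tau_m = tau_m,
            I0 = I0, Ia = Ia, eps = eps, gamma = gamma,
            n_grid = as.integer(n_grid), dt = dt, t_total = t_total,
            seed = seed, noise_corr_scale = noise_corr_scale,
            time_unit_ms = time_unit_ms)
  class(p) <- c("ring_params", "multistable_params")
  validate_params(p)
  p
}

#' @rdname ring_params
#' @export
reduced_params <- function(IR = 0.6, IL = 0.6, beta = 1, tau = 50,
                           eps = 0, dt = 1e-4, t_total = 1000,
                           seed = NULL, time_unit_ms = 10) {
  p <- list(IR = IR, IL = IL, beta = beta, tau = tau, eps = eps,
            dt = dt, t_total = t_total, seed = seed,
            time_unit_ms = time_unit_ms)
  class(p) <- c("reduced_params", "multistable_params")
  validate_params(p)
  p
}

#' @rdname ring_params
#' @export
tristable_params <- function(I = 0.6, beta = 1, tau = 50, eps = 0,
                             dt = 1e-4, t_total = 1000, seed = NULL,
                             time_unit_ms = 10) {
  p <- list(I = I, beta = beta, tau = tau, eps = eps, dt = dt,
            t_total = t_total, seed = seed, time_unit_ms = time_unit_ms)
  class(p) <- c("tristable_params", "multistable_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(p$beta >= 0, p$eps >= 0, p$dt > 0, p$t_total > 0,
            p$tau > 0, p$time_unit_ms > 0)
  if (!is.null(p$seed))
    stopifnot(is.numeric(p$seed), length(p$seed) == 1)
  if (inherits(p, "ring_params")) {
    stopifnot(p$kappa > 0, p$tau_m > 0, p$tau > p$tau_m,
              p$n_grid >= 8, p$n_grid <= 4096,
              p$noise_corr_scale > 0)
  } else {
    stopifnot(p$tau > 1)
  }
  invisible(p)
}

#' @export
print.multistable_params <- function(x, ...) {
  cls <- class(x)[1]
  cat("<", cls, ">\n", sep = "")
  flds <- vapply(x, function(v) if (is.null(v)) "NULL" else format(v), "")
  cat(paste0("  ", names(flds), " = ", flds, collapse = "\n"), "\n")
  invisible(x)
}

# model-unit -> seconds conversion used throughout
to_seconds <- function(t, time_unit_ms) t * time_unit_ms / 1000
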