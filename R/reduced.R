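#' Simulate the two-population mutual-inhibition network
#'
#' Euler--Maruyama integration of the space-free competitive network
#' \deqn{\dot u_R = -u_R + H(I_R - q_L u_L) + \xi_1, \qquad
#'       \dot u_L = -u_L + H(I_L - q_R u_R) + \xi_2,}
#' \deqn{\tau \dot q_j = 1 - q_j - \beta u_j q_j,}
#' with independent white noise of variance `eps` on the activity
#' variables only. Unless an explicit initial state is given, the
#' activities are drawn uniformly on \eqn{[0,1]} and the resources
#' uniformly on \eqn{[1/(1+\beta), 1]}.
#'
#' @param params a [reduced_params()] object.
#' @param init optional `list(u = c(uR, uL), q = c(qR, qL))`.
#' @param record_dt recording interval, model units.
#' @param min_dwell,burn_in see [detect_dominance()].
#' @return Object of class `"reduced_sim"`: list with `params`,
#'   `trajectory` (tibble `t`, `uR`, `uL`, `qR`, `qL`), `records`.
#' @examples
#' p <- reduced_params(IR = 0.6, IL = 0.6, beta = 1, t_total = 400,
#'                     seed = 1)
#' simulate_reduced(p)$records
#' @export
simulate_reduced <- function(params, init = NULL, record_dt = 0.01,
                             min_dwell = 0.5, burn_in = 50) {
  stopifnot(inherits(params, "reduced_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(init))
    init <- list(u = runif(2),
                 q = runif(2, 1 / (1 + params$beta), 1))
  n_steps <- round(params$t_total / params$dt)
  stride <- max(1L, as.integer(round(record_dt / params$dt)))
  raw <- reduced_sim_cpp(params$dt, n_steps, params$tau, params$beta,
                         params$IR, params$IL, params$eps,
                         init$u, init$q, stride)
  traj <- tibble::as_tibble(raw)
  recs <- detect_dominance(
    dplyr::transmute(traj, t = .data$t, R = .data$uR, L = .data$uL),
    min_dwell, burn_in, params$time_unit_ms)
  structure(list(params = params, trajectory = traj, records = recs),
            class = "reduced_sim")
}

#' Fast-slow dominance times of the reduced network
#'
#' In the adiabatic limit the activities are 0/1 almost everywhere and
#' switching occurs by escape when the depressing inhibitory synapse of
#' the dominant population weakens to the suppressed population's
#' input: the pre-switch resource of the right population is
#' \eqn{q_R = I_L} (and \eqn{q_L = I_R}). The dominance times follow
#' from the same two-phase slow flow as [dominance_time_ring()].
#' Rivalrous oscillations require
#' \eqn{I \in (1/(1+\beta), 2/(2+\beta))} for symmetric inputs (the
#' oscillation merges with the fusion state at the upper bound, 2/3 for
#' \eqn{\beta = 1}); outside the regime `exists = FALSE` is returned.
#'
#' @param IR,IL input strengths.
#' @param beta depletion rate.
#' @param tau recovery timescale.
#' @param time_unit_ms milliseconds per model unit.
#' @return One-row tibble: `exists`, `T_R`, `T_L`, `T_R_s`, `T_L_s`.
#' @examples
#' dominance_time_reduced(0.6, 0.6, beta = 1, tau = 50)
#' @export
dominance_time_reduced <- function(IR, IL, beta, tau, time_unit_ms = 10) {
  out <- slow_flow_period(IL, IR, beta, tau)
  out$T_R_s <- to_seconds(out$T_R, time_unit_ms)
  out$T_L_s <- to_seconds(out$T_L, time_unit_ms)
  out
}

#' Fixed-point regimes of the reduced network
#'
#' Classifies the attractor structure from the Heaviside fixed-point
#' conditions: a winner-take-all state with population j active exists
#' for \eqn{I_j > 0} and \eqn{I_k < 1/(1+\beta)}; the fusion state
#' (both active) exists when both inputs exceed \eqn{1/(1+\beta)};
#' rivalrous oscillations exist where the slow-flow periodic orbit of
#' [dominance_time_reduced()] exists. Labels: `winner_take_all`,
#' `rivalry` (oscillation present; the fusion fixed point coexists with
#' it, flagged in `fusion_fp`), `fusion_only`, `quiescent`.
#'
#' @inheritParams dominance_time_reduced
#' @return One-row tibble with `label`, `wta_right`, `wta_left`,
#'   `fusion_fp`, `oscillation`.
#' @examples
#' fixed_point_regimes(0.6, 0.3, beta = 1)   # right winner-take-all
#' fixed_point_regimes(0.8, 0.8, beta = 1)   # fusion only
#' @export
fixed_point_regimes <- function(IR, IL, beta) {
  qmin <- 1 / (1 + beta)
  wta_R <- IR > 0 && IL < qmin
  wta_L <- IL > 0 && IR < qmin
  fusion <- IR > qmin && IL > qmin
  osc <- isTRUE(slow_flow_period(IL, IR, beta, tau = 1)$exists)
  label <-
    if (wta_R || wta_L) "winner_take_all"
    else if (osc) "rivalry"
    else if (fusion) "fusion_only"
    else "quiescent"
  tibble::tibble(label = label, wta_right = wta_R, wta_left = wta_L,
                 fusion_fp = fusion, oscillation = osc)
}

#' Adiabatic energy of the reduced network
#'
#' Evaluates the Hopfield-style energy adapted to slow synaptic
#' depression,
#' \deqn{E = H(I_L - q_R u_R) H(I_R - q_L u_L)
#'   - I_L q_R H(I_L - q_R u_R) - I_R q_L H(I_R - q_L u_L),}
#' with \eqn{H(0) = 1}, together with the energy gaps separating each
#' winner-take-all state from fusion,
#' \eqn{\Delta E_R = 1 - I_L q_R} and \eqn{\Delta E_L = 1 - I_R q_L}.
#' Increasing one input lowers the barrier confining the *other*
#' population's dominant state, which is the energy-landscape reading
#' of Levelt's propositions for noise-driven switching.
#'
#' @param uR,uL activities.
#' @param qR,qL resource fractions.
#' @param IR,IL inputs.
#' @return Tibble (vectorized over the state arguments) with columns
#'   `E`, `dE_R`, `dE_L`.
#' @examples
#' energy(uR = 1, uL = 0, qR = 1, qL = 1, IR = 0.82, IL = 0.78)
#' @export
energy <- function(uR, uL, qR, qL, IR, IL) {
  H <- function(z) as.numeric(z >= 0)
  hR <- H(IL - qR * uR)
  hL <- H(IR - qL * uL)
  tibble::tibble(E = hR * hL - IL * qR * hR - IR * qL * hL,
                 dE_R = 1 - IL * qR,
                 dE_L = 1 - IR * qL)
}

#' @export
print.reduced_sim <- function(x, ...) {
  cat("<reduced_sim> ", x$params$t_total, " model units, ",
      nrow(x$records), " dominance epochs\n", sep = "")
  invisible(x)
}
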