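#' Simulate the three-population competitive network
#'
#' Integrates the tristable analog of the reduced network: three
#' populations with symmetric input `I`, each inhibited by the other
#' two through depressing synapses,
#' \deqn{\dot u_j = -u_j + H(I - \textstyle\sum_{k \ne j} q_k u_k) + \xi_j,
#'  \qquad \tau \dot q_j = 1 - q_j - \beta u_j q_j.}
#' Without noise, dominance cycles through the three percepts in a
#' fixed order set by the recovery state of the suppressed populations
#' (the population suppressed longest has recovered the most resources
#' and wins the escape); noise allows "switch-backs" that return to the
#' previous percept.
#'
#' @param params a [tristable_params()] object.
#' @param init optional `list(u = , q = )` of length-3 vectors.
#' @param record_dt recording interval, model units.
#' @param min_dwell,burn_in see [detect_dominance()].
#' @return Object of class `"tristable_sim"`: list with `params`,
#'   `trajectory` (tibble `t`, `u1..u3`, `q1..q3`), `records` (percept
#'   labels `"1"`, `"2"`, `"3"`).
#' @examples
#' p <- tristable_params(I = 0.6, beta = 1, t_total = 400, seed = 1)
#' simulate_tristable(p)$records
#' @export
simulate_tristable <- function(params, init = NULL, record_dt = 0.01,
                               min_dwell = 0.5, burn_in = 50) {
  stopifnot(inherits(params, "tristable_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(init))
    init <- list(u = runif(3), q = runif(3, 1 / (1 + params$beta), 1))
  n_steps <- round(params$t_total / params$dt)
  stride <- max(1L, as.integer(round(record_dt / params$dt)))
  raw <- tristable_sim_cpp(params$dt, n_steps, params$tau, params$beta,
                           params$I, params$eps, init$u, init$q, stride)
  traj <- tibble::tibble(t = raw$t,
                         u1 = raw$u[, 1], u2 = raw$u[, 2], u3 = raw$u[, 3],
                         q1 = raw$q[, 1], q2 = raw$q[, 2], q3 = raw$q[, 3])
  lab <- traj[, c("t", "u1", "u2", "u3")]
  names(lab) <- c("t", "1", "2", "3")
  recs <- detect_dominance(lab, min_dwell, burn_in, params$time_unit_ms)
  structure(list(params = params, trajectory = traj, records = recs),
            class = "tristable_sim")
}

#' Fast-slow dominance time of the tristable network
#'
#' Same adiabatic construction as [dominance_time_reduced()], with a
#' one-third duty cycle: each population is dominant for T (resource
#' depleting toward \eqn{1/(1+\beta)} at rate \eqn{(1+\beta)/\tau} until
#' it reaches the escape value \eqn{q = I}) and suppressed for 2T
#' (recovering at rate \eqn{1/\tau}).
#'
#' @param I common input strength.
#' @inheritParams dominance_time_reduced
#' @return One-row tibble: `exists`, `T`, `T_s`.
#' @examples
#' dominance_time_tristable(0.6, beta = 1, tau = 50)
#' @export
dominance_time_tristable <- function(I, beta, tau, time_unit_ms = 10) {
  out <- slow_flow_period(I, I, beta, tau, duty = 2)
  tibble::tibble(exists = out$exists, T = out$T_R,
                 T_s = to_seconds(out$T_R, time_unit_ms))
}

#' Switch-order statistics of tristable rivalry
#'
#' Classifies every consecutive percept triple of a dominance record
#' sequence as a *switch forward* (all three percepts distinct, e.g.
#' 1, 3, 2) or a *switch back* (first and third percepts equal, e.g.
#' 1, 3, 1), and reports the forward fraction
#' \eqn{p_f}. Without noise the depression memory enforces a fixed
#' cyclic order, so \eqn{p_f = 1}; with increasing noise the sequence
#' loses its history dependence and \eqn{p_f} falls toward the
#' Markovian value 1/2.
#'
#' @param records dominance records tibble (needs a `percept` column),
#'   or a plain vector of percept labels.
#' @return Object of class `"switch_stats"`: list with `p_f`,
#'   `n_forward`, `n_back`, and a `triples` tibble for audit.
#' @examples
#' switch_statistics(c("1", "2", "3", "1", "2"))$p_f   # 1
#' switch_statistics(c("1", "3", "1", "3"))$p_f        # 0
#' @export
switch_statistics <- function(records) {
  p <- if (is.data.frame(records)) records$percept else records
  p <- as.character(p)
  if (length(p) < 3) {
    out <- list(p_f = NA_real_, n_forward = 0L, n_back = 0L,
                triples = tibble::tibble(first = character(),
                                         second = character(),
                                         third = character(),
                                         kind = character()),
                insufficient = TRUE)
    class(out) <- "switch_stats"
    return(out)
  }
  n <- length(p)
  first <- p[seq_len(n - 2)]
  second <- p[seq(2, n - 1)]
  third <- p[seq(3, n)]
  kind <- ifelse(first == third, "back", "forward")
  out <- list(p_f = mean(kind == "forward"),
              n_forward = sum(kind == "forward"),
              n_back = sum(kind == "back"),
              triples = tibble::tibble(first, second, third, kind),
              insufficient = FALSE)
  class(out) <- "switch_stats"
  out
}

#' @export
print.switch_stats <- function(x, ...) {
  if (isTRUE(x$insufficient)) {
    cat("<switch_stats> fewer than 3 records; no statistics\n")
  } else {
    cat("<switch_stats> p_f =", format(x$p_f, digits = 4),
        sprintf("(%d forward / %d back)\n", x$n_forward, x$n_back))
  }
  invisible(x)
}

#' @export
print.tristable_sim <- function(x, ...) {
  cat("<tristable_sim> ", x$params$t_total, " model units, ",
      nrow(x$records), " dominance epochs\n", sep = "")
  invisible(x)
}
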