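#' Simulate the stochastic ring neural field
#'
#' Integrates the ring model
#' \deqn{\tau_m \dot u = -u + w*(q f(u)) + I(x) + \xi(x,t), \qquad
#'       \tau \dot q = 1 - q - \beta q f(u)}
#' with the cosine kernel, the bimodal stimulus of [bimodal_input()],
#' and spatially correlated noise (see [sample_noise()]) using the
#' Euler--Maruyama scheme. Setting `beta = 0` recovers the
#' depression-free stochastic field in which switching is purely
#' noise-driven. Peak activities of the two domain halves are recorded
#' every `record_dt` model units and passed to [detect_dominance()].
#'
#' Available initial-condition presets: `"wta_right"` / `"wta_left"`
#' (the stationary winner-take-all bump, the usual initial state),
#' `"fusion"` (the two-bump state), `"flat"` (u = q - 1 = 0), or a
#' `list(u = , q = )` of vectors of length `n_grid`.
#'
#' @param params a [ring_params()] object.
#' @param init preset name or `list(u, q)`.
#' @param record_dt interval between recorded peak samples (model
#'   units); must resolve the debounce dwell.
#' @param snapshot_dt if non-`NULL`, full u and q fields are stored at
#'   this interval (memory permitting).
#' @param min_dwell,burn_in dominance-detection settings, see
#'   [detect_dominance()].
#' @return Object of class `"ring_sim"`: list with elements `params`,
#'   `peaks` (tibble `t`, `peak_R`, `peak_L`), `records` (dominance
#'   epochs), `final` (list `x`, `u`, `q`), and optionally `snapshots`
#'   (long tibble `t`, `x`, `u`, `q`).
#' @examples
#' p <- ring_params(I0 = 0.84, beta = 1, eps = 0, n_grid = 128,
#'                  t_total = 300)
#' sim <- simulate_ring(p)
#' sim$records
#' @export
simulate_ring <- function(params, init = "wta_right", record_dt = 0.01,
                          snapshot_dt = NULL, min_dwell = 0.5,
                          burn_in = 50) {
  stopifnot(inherits(params, "ring_params"))
  st <- ring_init(params, init)
  n_steps <- round(params$t_total / params$dt)
  stride <- max(1L, as.integer(round(record_dt / params$dt)))
  snap_stride <- if (is.null(snapshot_dt)) 0L
    else max(1L, as.integer(round(snapshot_dt / params$dt)))
  gam <- if (is.infinite(params$gamma)) -1 else params$gamma
  if (!is.null(params$seed)) set.seed(params$seed)
  raw <- ring_sim_cpp(params$n_grid, params$dt, n_steps, params$tau_m,
                      params$tau, params$beta, params$kappa, gam,
                      params$I0, params$Ia, params$eps,
                      params$noise_corr_scale, st$u, st$q,
                      stride, snap_stride)
  peaks <- tibble::tibble(t = raw$t, peak_R = raw$peak_R,
                          peak_L = raw$peak_L)
  out <- list(
    params = params,
    peaks = peaks,
    records = detect_dominance(peaks, min_dwell, burn_in,
                               params$time_unit_ms),
    final = list(x = ring_grid(params$n_grid), u = raw$u_final,
                 q = raw$q_final))
  if (snap_stride > 0) {
    x <- ring_grid(params$n_grid)
    out$snapshots <- tibble::tibble(
      t = rep(raw$snap_t, each = length(x)),
      x = rep(x, times = length(raw$snap_t)),
      u = as.vector(t(raw$snap_u)),
      q = as.vector(t(raw$snap_q)))
  }
  class(out) <- "ring_sim"
  out
}

# construct the initial field state for a preset
ring_init <- function(params, init) {
  n <- params$n_grid
  x <- ring_grid(n)
  if (is.list(init)) {
    stopifnot(length(init$u) == n, length(init$q) == n)
    return(list(u = init$u, q = init$q))
  }
  beta <- params$beta
  qd <- 1 / (1 + beta)
  build_wta <- function(side) {
    Ia_eff <- side * params$Ia
    a <- wta_half_width(params$I0, Ia_eff, params$kappa, beta)
    if (is.na(a))
      stop("no winner-take-all bump exists at these parameters; ",
           "use init = \"flat\" or supply u and q directly")
    B <- side * sin(2 * a) / (1 + beta)
    u <- (B + params$Ia) * sin(2 * x) - params$I0 * cos(4 * x)
    q <- ifelse(abs(x - side * pi / 4) < a, qd, 1)
    list(u = u, q = q)
  }
  switch(init,
    wta_right = build_wta(1),
    wta_left = build_wta(-1),
    fusion = {
      fh <- fusion_half_widths(params$I0, params$Ia, params$kappa, beta)
      if (!isTRUE(fh$exists))
        stop("no fusion state exists at these parameters")
      D <- (sin(2 * fh$a) - sin(2 * fh$b)) / (1 + beta)
      u <- (D + params$Ia) * sin(2 * x) - params$I0 * cos(4 * x)
      q <- ifelse(abs(x - pi / 4) < fh$a | abs(x + pi / 4) < fh$b, qd, 1)
      list(u = u, q = q)
    },
    flat = list(u = rep(0, n), q = rep(1, n)),
    stop("unknown init preset: ", init))
}

#' @export
print.ring_sim <- function(x, ...) {
  cat("<ring_sim> ", x$params$t_total, " model units, n_grid = ",
      x$params$n_grid, ", ", nrow(x$records), " dominance epochs\n",
      sep = "")
  invisible(x)
}
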