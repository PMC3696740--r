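# brute-force O(n^2) quadrature of the cosine-kernel convolution,
# independent of the separable fast path
drive_direct <- function(u, q, kappa, gamma = Inf, x = NULL) {
  n <- length(u)
  if (is.null(x)) x <- ring_grid(n)
  f <- gain_fun(u, kappa, gamma)
  dx <- pi / n
  vapply(seq_len(n), function(i) sum(cos(2 * (x[i] - x)) * q * f) * dx, 0)
}

# short noise-free ring rivalry simulation; returns settled period
ring_period_sim <- function(I0, beta = 1, tau = 50, n_grid = 512,
                            dt = 1e-3, t_total = 700) {
  p <- ring_params(I0 = I0, beta = beta, tau = tau, eps = 0,
                   n_grid = n_grid, dt = dt, t_total = t_total)
  s <- simulate_ring(p)
  d <- s$records$duration[!s$records$censored]
  mean(tail(d, 4))
}

# numerical solution of the defining pre-switch system for the ring:
# threshold (q/2) sin 4a + I0 cos 4a + Ia cos 2a = kappa and escape
# I0 - Ia - q sin 2a = kappa, solved on a fine grid + polish
pre_switch_oracle <- function(I0, Ia, kappa) {
  res <- function(v) {
    q <- v[1]; a <- v[2]
    c(q / 2 * sin(4 * a) + I0 * cos(4 * a) + Ia * cos(2 * a) - kappa,
      I0 - Ia - q * sin(2 * a) - kappa)
  }
  # eliminate q from the escape equation and scan a
  g <- function(a) {
    q <- (I0 - Ia - kappa) / sin(2 * a)
    q / 2 * sin(4 * a) + I0 * cos(4 * a) + Ia * cos(2 * a) - kappa
  }
  as <- seq(1e-4, pi / 4 - 1e-4, length.out = 4000)
  gv <- vapply(as, g, 0)
  i <- which(gv[-1] * gv[-length(gv)] <= 0)[1]
  if (is.na(i)) return(NULL)
  a <- uniroot(g, c(as[i], as[i + 1]), tol = 1e-14)$root
  q <- (I0 - Ia - kappa) / sin(2 * a)
  stopifnot(max(abs(res(c(q, a)))) < 1e-10)
  list(q = q, a = a)
}
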