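#' Winner-take-all bump of the ring model
#'
#' `wta_half_width()` solves the threshold condition of the stationary
#' single-bump (winner-take-all) state,
#' \deqn{\frac{\sin 4a}{2(1+\beta)} + I_0\cos 4a + I_a\cos 2a = \kappa,}
#' for the bump half-width \eqn{a \in (0, \pi/4)} by bracketed
#' root-finding; when several roots exist the largest (the stable, wider
#' bump) is returned. For symmetric inputs the explicit formula
#' \deqn{a = \tfrac12\tan^{-1}\!\Big[\frac{1+\sqrt{1+4(1+\beta)^2(I_0^2-\kappa^2)}}{2(1+\beta)(I_0+\kappa)}\Big]}
#' gives the same value (checked in the test-suite to 1e-10).
#'
#' `wta_exists()` additionally tests the suppressed-side condition: the
#' bump state exists only while the local maximum of U at the opposite
#' stimulus peak stays subthreshold,
#' \eqn{U(-\pi/4) = I_0 - I_a - \sin(2a)/(1+\beta) < \kappa}. The margin
#' \eqn{\kappa - U(-\pi/4)} is positive when the state exists; it
#' vanishes on the bifurcation boundary
#' \eqn{I_0 = \kappa + I_a + \sin(2a)/(1+\beta)}.
#'
#' @param I0,Ia stimulus amplitudes (right peak \eqn{I_0+I_a}).
#' @param kappa firing threshold.
#' @param beta depression depletion rate.
#' @return `wta_half_width()`: the half-width in radians (`NA` if no
#'   root exists in \eqn{(0,\pi/4)}). `wta_exists()`: a one-row tibble
#'   with columns `exists`, `margin`, `half_width`, `residual`.
#' @examples
#' wta_exists(I0 = 0.6, kappa = 0.5, beta = 1)   # winner-take-all
#' wta_exists(I0 = 0.84, kappa = 0.5, beta = 1)  # rivalry regime
#' @export
wta_half_width <- function(I0, Ia = 0, kappa, beta) {
  h <- function(a)
    sin(4 * a) / (2 * (1 + beta)) + I0 * cos(4 * a) + Ia * cos(2 * a) - kappa
  largest_root(h, 0, pi / 4)
}

#' @rdname wta_half_width
#' @export
wta_exists <- function(I0, Ia = 0, kappa, beta) {
  a <- wta_half_width(I0, Ia, kappa, beta)
  if (is.na(a))
    return(tibble::tibble(exists = FALSE, margin = NA_real_,
                          half_width = NA_real_, residual = NA_real_))
  suppressed <- I0 - Ia - sin(2 * a) / (1 + beta)
  res <- sin(4 * a) / (2 * (1 + beta)) + I0 * cos(4 * a) +
    Ia * cos(2 * a) - kappa
  tibble::tibble(exists = suppressed < kappa, margin = kappa - suppressed,
                 half_width = a, residual = res)
}

#' Fusion (two-bump) state of the ring model
#'
#' Solves the pair of threshold conditions
#' \eqn{U(\pi/4 \pm a) = U(-\pi/4 \pm b) = \kappa} for the half-widths
#' (a, b) of the simultaneous right and left bumps, where
#' \deqn{U(x) = \Big[\frac{\sin 2a - \sin 2b}{1+\beta} + I_a\Big]\sin 2x
#'   - I_0\cos 4x.}
#' For symmetric inputs the solution is \eqn{a = b =
#' \tfrac14\cos^{-1}(\kappa/I_0)}; for asymmetric inputs the 2x2 system
#' is solved by damped Newton iteration started from the symmetric
#' value.
#'
#' @inheritParams wta_half_width
#' @return One-row tibble with columns `exists`, `a`, `b`,
#'   `residual_a`, `residual_b`.
#' @export
fusion_half_widths <- function(I0, Ia = 0, kappa, beta) {
  none <- tibble::tibble(exists = FALSE, a = NA_real_, b = NA_real_,
                         residual_a = NA_real_, residual_b = NA_real_)
  if (I0 < kappa) return(none)
  Fab <- function(ab) {
    D <- (sin(2 * ab[1]) - sin(2 * ab[2])) / (1 + beta) + Ia
    c(D * cos(2 * ab[1]) + I0 * cos(4 * ab[1]) - kappa,
      -D * cos(2 * ab[2]) + I0 * cos(4 * ab[2]) - kappa)
  }
  a0 <- acos(min(1, kappa / I0)) / 4
  ab <- c(a0, a0)
  if (Ia != 0) {
    ok <- FALSE
    for (it in 1:100) {
      Fv <- Fab(ab)
      if (max(abs(Fv)) < 1e-13) { ok <- TRUE; break }
      # finite-difference Jacobian; the system is smooth and well scaled
      h <- 1e-7
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        abh <- ab; abh[j] <- abh[j] + h
        J[, j] <- (Fab(abh) - Fv) / h
      }
      step <- tryCatch(solve(J, Fv), error = function(e) NULL)
      if (is.null(step)) return(none)
      ab <- ab - pmin(pmax(step, -0.1), 0.1)
      if (any(!is.finite(ab)) || any(ab <= 0) || any(ab >= pi / 4))
        return(none)
    }
    if (!ok && max(abs(Fab(ab))) > 1e-9) return(none)
  }
  Fv <- Fab(ab)
  tibble::tibble(exists = TRUE, a = ab[1], b = ab[2],
                 residual_a = Fv[1], residual_b = Fv[2])
}

#' Pre-switch depression values of the rivalrous oscillation
#'
#' During a rivalrous oscillation the dominant bump slowly narrows as
#' its synaptic resources deplete; the suppressed bump escapes when the
#' stimulus peak on its side reaches threshold. Combining the moving
#' threshold condition
#' \eqn{\tfrac{q}{2}\sin 4a + I_0\cos 4a + I_a\cos 2a = \kappa}
#' with the escape condition
#' \eqn{I_0 - I_a - q\sin 2a = \kappa} gives the half-width at the
#' switch, \eqn{a_0 = \tfrac12\cos^{-1}[\kappa/(2I_0) + \tfrac12]}
#' (independent of \eqn{I_a}), and the resource values inside the
#' dominant bump immediately before its suppression:
#' \deqn{q_R = \frac{2 I_0 (I_L - \kappa)}{\sqrt{(3I_0+\kappa)(I_0-\kappa)}},
#' \qquad q_L = \frac{2 I_0 (I_R - \kappa)}{\sqrt{(3I_0+\kappa)(I_0-\kappa)}},}
#' with \eqn{I_{R,L} = I_0 \pm I_a}; for symmetric inputs both reduce to
#' \eqn{q_0 = 2 I_0 \sqrt{(I_0-\kappa)/(3I_0+\kappa)}}. These closed
#' forms are verified against a direct numerical solution of the
#' defining two-equation system in the test-suite.
#'
#' An oscillation exists only while the pre-switch values are reachable
#' by the depression dynamics, \eqn{q \in (1/(1+\beta), 2/(2+\beta))};
#' the upper bound is where the period of the self-consistent slow flow
#' shrinks to zero and the oscillation merges with the fusion state (see
#' [dominance_time_ring()]).
#'
#' @inheritParams wta_half_width
#' @return One-row tibble with columns `q0`, `qR`, `qL`, `a0`.
#' @export
pre_switch_resources <- function(I0, Ia = 0, kappa) {
  if (I0 <= kappa)
    return(tibble::tibble(q0 = NA_real_, qR = NA_real_, qL = NA_real_,
                          a0 = NA_real_))
  a0 <- acos(kappa / (2 * I0) + 0.5) / 2
  den <- sqrt((3 * I0 + kappa) * (I0 - kappa))
  tibble::tibble(
    q0 = 2 * I0 * sqrt((I0 - kappa) / (3 * I0 + kappa)),
    qR = 2 * I0 * (I0 - Ia - kappa) / den,
    qL = 2 * I0 * (I0 + Ia - kappa) / den,
    a0 = a0)
}

#' Fast-slow dominance times of the ring model
#'
#' Adiabatic (fast-slow) theory of the rivalrous oscillation: for
#' \eqn{\tau \gg \tau_m} the activity profile tracks the slowly varying
#' depression field, and the dominance time follows from the two-phase
#' relaxation of the resource inside a bump. During its dominance phase
#' (duration \eqn{T_R}) the resource relaxes toward \eqn{1/(1+\beta)}
#' with rate \eqn{(1+\beta)/\tau}; while suppressed (duration
#' \eqn{T_L}) it recovers toward 1 with rate \eqn{1/\tau}. Requiring the
#' periodic orbit to start and end each phase at the pre-switch values
#' \eqn{q_R, q_L} of [pre_switch_resources()] yields two equations in
#' \eqn{z_R = e^{-T_R/\tau}, z_L = e^{-T_L/\tau}}:
#' \deqn{q_R = \frac{1}{1+\beta} + \Big(\frac{\beta}{1+\beta} +
#'   (q_R - 1) z_L\Big) z_R^{1+\beta}}
#' and the mirror equation with R and L exchanged. The symmetric case
#' reduces to a single scalar root; the asymmetric system is solved by
#' eliminating \eqn{z_L} and root-finding in \eqn{z_R}. Solutions are
#' polished to residuals below 1e-12.
#'
#' The interior root exists only for pre-switch values in
#' \eqn{(1/(1+\beta), 2/(2+\beta))}; outside that range no rivalrous
#' orbit exists and `NA` is returned with `exists = FALSE`. The theory
#' is leading-order in \eqn{\tau_m/\tau}: its error against noise-free
#' simulation decays like \eqn{O(\tau_m/\tau)} (a few percent at
#' \eqn{\tau = 50}, below 1% by \eqn{\tau \approx 400}).
#'
#' @inheritParams wta_half_width
#' @param tau depression recovery timescale (model units).
#' @param time_unit_ms milliseconds per model unit for the `_s` columns.
#' @return One-row tibble: `exists`, `T_R`, `T_L` (model units),
#'   `T_R_s`, `T_L_s` (seconds).
#' @examples
#' dominance_time_ring(I0 = 0.84, kappa = 0.5, beta = 1, tau = 50)
#' @export
dominance_time_ring <- function(I0, Ia = 0, kappa, beta, tau,
                                time_unit_ms = 10) {
  q <- pre_switch_resources(I0, Ia, kappa)
  out <- slow_flow_period(q$qR, q$qL, beta, tau)
  out$T_R_s <- to_seconds(out$T_R, time_unit_ms)
  out$T_L_s <- to_seconds(out$T_L, time_unit_ms)
  out
}

#' Partition of the (beta, I0) parameter plane into stimulus-driven regimes
#'
#' Classifies every point of a `beta` x `I0` grid into one of
#' `winner_take_all`, `rivalry`, `fusion`, or `no_active_state`:
#' winner-take-all where the single-bump state exists
#' ([wta_exists()]); otherwise rivalry where the pre-switch resource
#' value is reachable, \eqn{q_0 \in (1/(1+\beta), 2/(2+\beta))};
#' otherwise fusion where the two-bump state exists
#' ([fusion_half_widths()]); otherwise quiescent.
#'
#' @param beta,I0 numeric vectors spanning the grid.
#' @inheritParams dominance_time_ring
#' @return Tibble of class `"regime_grid"` with columns `beta`, `I0`,
#'   `label`, `half_width`, `q0`, `wta_margin`, and the rivalry period
#'   `T` (model units, `NA` outside the rivalry regime).
#' @examples
#' regime_partition(beta = 1, I0 = c(0.6, 0.84, 1.0), kappa = 0.5)
#' @export
regime_partition <- function(beta, I0, kappa = 0.5, tau = 50) {
  grid <- tidyr::expand_grid(beta = beta, I0 = I0)
  out <- purrr::pmap_dfr(grid, function(beta, I0) {
    w <- wta_exists(I0, 0, kappa, beta)
    q <- pre_switch_resources(I0, 0, kappa)
    rivalry <- !is.na(q$q0) &&
      q$q0 > 1 / (1 + beta) && q$q0 < 2 / (2 + beta)
    label <-
      if (isTRUE(w$exists)) "winner_take_all"
      else if (rivalry) "rivalry"
      else if (isTRUE(fusion_half_widths(I0, 0, kappa, beta)$exists)) "fusion"
      else "no_active_state"
    Tv <- if (label == "rivalry")
      dominance_time_ring(I0, 0, kappa, beta, tau)$T_R else NA_real_
    tibble::tibble(beta = beta, I0 = I0, label = label,
                   half_width = w$half_width, q0 = q$q0,
                   wta_margin = w$margin, T = Tv)
  })
  class(out) <- c("regime_grid", class(out))
  out
}

# ---- internal helpers -------------------------------------------------

# largest sign-change root of f on (lo, hi); NA if none
largest_root <- function(f, lo, hi, n_scan = 2048, tol = 1e-14) {
  a <- seq(lo + (hi - lo) * 1e-9, hi - (hi - lo) * 1e-9,
           length.out = n_scan)
  v <- vapply(a, f, 0)
  s <- which(v[-1] * v[-n_scan] <= 0 & is.finite(v[-1]) & is.finite(v[-n_scan]))
  if (!length(s)) return(NA_real_)
  i <- max(s)
  uniroot(f, c(a[i], a[i + 1]), tol = tol)$root
}

# Two-phase slow-flow periodic orbit for given pre-switch resource
# values.  duty = number of dominance periods spent suppressed between
# two dominance phases (1 for two populations, 2 for three).
slow_flow_period <- function(q_sw_R, q_sw_L = q_sw_R, beta, tau, duty = 1) {
  none <- tibble::tibble(exists = FALSE, T_R = NA_real_, T_L = NA_real_)
  if (any(is.na(c(q_sw_R, q_sw_L)))) return(none)
  qmin <- 1 / (1 + beta)
  if (q_sw_R <= qmin || q_sw_L <= qmin || q_sw_R >= 1 || q_sw_L >= 1)
    return(none)

  if (q_sw_R == q_sw_L) {
    f <- function(z)
      qmin + (beta / (1 + beta) + (q_sw_R - 1) * z^duty) * z^(1 + beta) - q_sw_R
    z <- interior_root01(f)
    if (is.na(z)) return(none)
    T <- -tau * log(z)
    return(tibble::tibble(exists = TRUE, T_R = T, T_L = T))
  }

  # asymmetric two-population cycle: eliminate z_L from the R equation
  zL_of <- function(zR) {
    ((q_sw_R - qmin) / zR^(1 + beta) - beta / (1 + beta)) / (q_sw_R - 1)
  }
  g <- function(zR) {
    zL <- zL_of(zR)
    if (!is.finite(zL) || zL <= 0 || zL >= 1) return(NA_real_)
    qmin + (beta / (1 + beta) + (q_sw_L - 1) * zR) * zL^(1 + beta) - q_sw_L
  }
  zs <- seq(1e-6, 1 - 1e-6, length.out = 4096)
  gv <- vapply(zs, g, 0)
  ok <- which(!is.na(gv))
  if (length(ok) < 2) return(none)
  idx <- ok[which(gv[ok][-1] * gv[ok][-length(ok)] <= 0)]
  root <- NA_real_
  for (i in idx) {
    j <- ok[which(ok > i)][1]
    if (is.na(j)) next
    r <- tryCatch(uniroot(g, c(zs[i], zs[j]), tol = 1e-14)$root,
                  error = function(e) NA_real_)
    zl <- if (is.na(r)) NA_real_ else zL_of(r)
    # discard the degenerate branch near z = 1 (zero-period orbit)
    if (!is.na(r) && !is.na(zl) && r < 1 - 1e-6 && zl < 1 - 1e-6) {
      root <- r; break
    }
  }
  if (is.na(root)) return(none)
  tibble::tibble(exists = TRUE, T_R = -tau * log(root),
                 T_L = -tau * log(zL_of(root)))
}

# interior root of f on (0,1); z = 1 is always a trivial root, so scan
# for the sign change strictly inside
interior_root01 <- function(f, n_scan = 4096) {
  z <- seq(1e-7, 1 - 1e-5, length.out = n_scan)
  v <- vapply(z, f, 0)
  s <- which(v[-1] * v[-n_scan] <= 0)
  if (!length(s)) return(NA_real_)
  uniroot(f, c(z[s[1]], z[s[1] + 1]), tol = 1e-14)$root
}
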