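#' Registered figure-level experiments
#'
#' Each experiment drives the simulators and statistics end to end and
#' returns a result bundle: a one-row `summary` tibble with the
#' headline statistic plus named `artifacts` (records, fits, traces).
#' `experiments()` lists the registry. All randomness derives from the
#' single `seed` argument, so a rerun with the same seed and scale
#' reproduces every output exactly.
#'
#' The `"desk"` scale uses n_grid = 512, dt = 1e-3 for the ring
#' (dt = 1e-4 for the space-free networks) and pools a few thousand
#' model-time units per replicate; `"full_res"` restores the
#' full-resolution settings (ring dt = 1e-4 with 2000 grid points,
#' reduced dt = 1e-6) at substantially higher cost.
#'
#' @param name experiment name, see `experiments()`.
#' @param seed integer master seed.
#' @param scale `"desk"` or `"full_res"`.
#' @param out_dir if non-`NULL`, results are written there: a params
#'   JSON sidecar, dominance CSVs, fit JSONs and a summary JSON.
#' @param ... overrides forwarded to the experiment function (e.g.
#'   `target_epochs`).
#' @return Invisibly for `experiments()`, a tibble of names and
#'   descriptions; `run_experiment()` returns the result bundle.
#' @examples
#' experiments()
#' r <- run_experiment("tristable_demo", seed = 1,
#'                     target_switches = 20)
#' r$summary
#' @export
run_experiment <- function(name, seed = 1, scale = c("desk", "full_res"),
                           out_dir = NULL, ...) {
  scale <- match.arg(scale)
  reg <- experiment_registry()
  if (!name %in% names(reg))
    stop("unknown experiment: ", name, ". See experiments().")
  t0 <- Sys.time()
  res <- reg[[name]]$fn(seed = seed, scale = scale, ...)
  res$name <- name
  res$seed <- seed
  res$scale <- scale
  res$runtime_s <- as.numeric(Sys.time() - t0, units = "secs")
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

#' @rdname run_experiment
#' @export
experiments <- function() {
  reg <- experiment_registry()
  tibble::tibble(name = names(reg),
                 description = vapply(reg, function(e) e$desc, ""))
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok_marker <- file.path(out_dir, "INCOMPLETE")
  file.create(ok_marker)
  meta <- list(name = res$name, seed = res$seed, scale = res$scale,
               runtime_s = res$runtime_s,
               package_version = as.character(utils::packageVersion("multistable")),
               params = res$params)
  jsonlite::write_json(meta, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(res$artifacts)) {
    a <- res$artifacts[[nm]]
    if (is.data.frame(a) && "percept" %in% names(a) &&
        "duration" %in% names(a)) {
      if (!"censored" %in% names(a)) a$censored <- FALSE
      write_dominance_csv(a, file.path(out_dir, paste0(nm, ".csv")))
    } else if (is.data.frame(a)) {
      readr::write_csv(a, file.path(out_dir, paste0(nm, ".csv")))
    } else if (inherits(a, "dominance_fit")) {
      jsonlite::write_json(
        c(list(family = a$family), glance(a), as.list(tidy(a)$estimate)),
        file.path(out_dir, paste0(nm, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(as.list(res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  file.remove(ok_marker)
  invisible(out_dir)
}

# one ring parameter set per scale
ring_scale <- function(scale, ...) {
  base <- if (scale == "desk")
    list(n_grid = 512, dt = 1e-3, t_total = 3000)
  else
    list(n_grid = 2000, dt = 1e-4, t_total = 20000)
  do.call(ring_params, utils::modifyList(base, list(...)))
}

experiment_registry <- function() {
  list(
    noise_only_symmetric = list(
      desc = "Depression-free ring, symmetric input: exponential dominance times",
      fn = exp_noise_only_symmetric),
    symmetric_inference = list(
      desc = "Contrast-inference trace for symmetric inputs (limit 1/2)",
      fn = exp_symmetric_inference),
    asymmetric_inference = list(
      desc = "Depression-free ring, asymmetric inputs: means, exponential fits, inference",
      fn = exp_asymmetric_inference),
    depression_noise_gamma = list(
      desc = "Ring with depression + noise: gamma-shaped dominance histograms",
      fn = exp_depression_noise_gamma),
    reduced_demo = list(
      desc = "Two-population network with depression + noise: gamma fits",
      fn = exp_reduced_demo),
    fastslow_check = list(
      desc = "Adiabatic dominance-time theory vs noise-free simulation",
      fn = exp_fastslow_check),
    regime_map = list(
      desc = "Partition of the (beta, I0) plane into regimes",
      fn = exp_regime_map),
    tristable_demo = list(
      desc = "Three-population rivalry: cyclic order and switch-backs",
      fn = exp_tristable_demo),
    pf_noise_sweep = list(
      desc = "Forward-switch probability p_f vs noise amplitude",
      fn = exp_pf_noise_sweep))
}

exp_noise_only_symmetric <- function(seed, scale, target_epochs = 500,
                                     n_seeds = 80) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_seeds)
  p <- ring_scale(scale, beta = 0, I0 = 0.9, Ia = 0, kappa = 0.5,
                  eps = 0.04)
  rec <- pool_ring_epochs(p, seeds, target_epochs = target_epochs)
  fit <- fit_exponential(rec)
  list(params = p[setdiff(names(p), "seed")],
       summary = tibble::tibble(mean_T = fit$mean_T,
                                mean_T_s = to_seconds(fit$mean_T, p$time_unit_ms),
                                n_epochs = nrow(rec),
                                ks_distance = fit$ks_distance),
       artifacts = list(dominance = rec, exp_fit = fit))
}

exp_symmetric_inference <- function(seed, scale, target_cycles = 200,
                                    n_seeds = 80) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_seeds)
  p <- ring_scale(scale, beta = 0, I0 = 0.9, Ia = 0, kappa = 0.5,
                  eps = 0.04)
  rec <- pool_ring_epochs(p, seeds, target_cycles = target_cycles)
  inf <- inference_probability(rec)
  list(params = p[setdiff(names(p), "seed")],
       summary = tibble::tibble(p_inf = inf$p_inf,
                                p_final = tail(inf$trace$p_n, 1),
                                n_cycles = inf$n_cycles),
       artifacts = list(dominance = rec, trace = inf$trace))
}

exp_asymmetric_inference <- function(seed, scale, target_cycles = 500,
                                     n_seeds = 120) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_seeds)
  p <- ring_scale(scale, beta = 0, I0 = 0.9, Ia = 0.02, kappa = 0.5,
                  eps = 0.04)
  rec <- pool_ring_epochs(p, seeds, target_cycles = target_cycles)
  fitR <- fit_exponential(rec[rec$percept == "R", ])
  fitL <- fit_exponential(rec[rec$percept == "L", ])
  inf <- inference_probability(rec)
  list(params = p[setdiff(names(p), "seed")],
       summary = tibble::tibble(
         mean_T_R_s = to_seconds(fitR$mean_T, p$time_unit_ms),
         mean_T_L_s = to_seconds(fitL$mean_T, p$time_unit_ms),
         ks_R = fitR$ks_distance, ks_L = fitL$ks_distance,
         p_inf = inf$p_inf, n_cycles = inf$n_cycles),
       artifacts = list(dominance = rec, exp_fit_R = fitR,
                        exp_fit_L = fitL, trace = inf$trace))
}

exp_depression_noise_gamma <- function(seed, scale, target_epochs = 400,
                                       n_seeds = 60) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_seeds)
  p <- ring_scale(scale, beta = 0.2, tau = 50, I0 = 0.9, Ia = 0.02,
                  kappa = 0.5, eps = 0.01)
  rec <- pool_ring_epochs(p, seeds, target_epochs = target_epochs)
  fits <- lapply(c(R = "R", L = "L"), function(s) {
    tryCatch(fit_gamma_3point(rec[rec$percept == s, ]),
             error = function(e) NULL)
  })
  list(params = p[setdiff(names(p), "seed")],
       summary = tibble::tibble(
         mean_T_R_s = to_seconds(mean(rec$duration[rec$percept == "R"]),
                                 p$time_unit_ms),
         mean_T_L_s = to_seconds(mean(rec$duration[rec$percept == "L"]),
                                 p$time_unit_ms),
         shape_std_R = if (is.null(fits$R)) NA_real_ else fits$R$shape_std,
         shape_std_L = if (is.null(fits$L)) NA_real_ else fits$L$shape_std,
         n_epochs = nrow(rec)),
       artifacts = c(list(dominance = rec),
                     Filter(Negate(is.null),
                            list(gamma_fit_R = fits$R,
                                 gamma_fit_L = fits$L))))
}

exp_reduced_demo <- function(seed, scale, t_total = 10000) {
  p <- reduced_params(IR = 0.82, IL = 0.78, beta = 0.2, tau = 50,
                      eps = 0.036,
                      dt = if (scale == "desk") 1e-4 else 1e-6,
                      t_total = t_total, seed = seed)
  sim <- simulate_reduced(p)
  rec <- sim$records[!sim$records$censored, ]
  mR <- mean(rec$duration[rec$percept == "R"])
  mL <- mean(rec$duration[rec$percept == "L"])
  list(params = p[setdiff(names(p), "seed")],
       summary = tibble::tibble(
         mean_T_R_s = to_seconds(mR, p$time_unit_ms),
         mean_T_L_s = to_seconds(mL, p$time_unit_ms),
         n_epochs = nrow(rec)),
       artifacts = list(dominance = rec))
}

exp_fastslow_check <- function(seed, scale,
                               ring_I0 = c(0.80, 0.82, 0.84, 0.86),
                               reduced_I = c(0.55, 0.58, 0.60, 0.63),
                               tristable_I = 0.6) {
  rows <- list()
  for (I0 in ring_I0) {
    th <- dominance_time_ring(I0, 0, kappa = 0.5, beta = 1, tau = 50)
    p <- ring_params(I0 = I0, beta = 1, tau = 50, eps = 0,
                     n_grid = if (scale == "desk") 512 else 2000,
                     dt = if (scale == "desk") 1e-3 else 1e-4,
                     t_total = 700)
    sim <- simulate_ring(p)
    Ts <- steady_period(sim$records)
    rows[[length(rows) + 1]] <- tibble::tibble(
      model = "ring", input = I0, T_theory = th$T_R, T_sim = Ts)
  }
  for (I in reduced_I) {
    th <- dominance_time_reduced(I, I, beta = 1, tau = 50)
    p <- reduced_params(IR = I, IL = I, beta = 1, tau = 50, eps = 0,
                        t_total = 1500, seed = seed)
    sim <- simulate_reduced(p, init = list(u = c(1, 0), q = c(0.7, 0.9)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      model = "reduced", input = I, T_theory = th$T_R,
      T_sim = steady_period(sim$records))
  }
  for (I in tristable_I) {
    th <- dominance_time_tristable(I, beta = 1, tau = 50)
    p <- tristable_params(I = I, beta = 1, tau = 50, eps = 0,
                          t_total = 1500, seed = seed)
    sim <- simulate_tristable(p, init = list(u = c(1, 0, 0),
                                             q = c(0.6, 0.8, 1)))
    rows[[length(rows) + 1]] <- tibble::tibble(
      model = "tristable", input = I, T_theory = th$T,
      T_sim = steady_period(sim$records))
  }
  tab <- dplyr::bind_rows(rows)
  tab$rel_err <- tab$T_theory / tab$T_sim - 1
  list(params = list(kappa = 0.5, beta = 1, tau = 50),
       summary = tibble::tibble(max_abs_rel_err = max(abs(tab$rel_err))),
       artifacts = list(comparison = tab))
}

# mean duration over the last few (settled) full epochs of a
# noise-free oscillation
steady_period <- function(records, k = 4) {
  d <- records$duration[!records$censored]
  mean(tail(d, k))
}

exp_regime_map <- function(seed, scale,
                           beta = seq(0.2, 2, by = 0.2),
                           I0 = seq(0.45, 1.2, by = 0.05)) {
  grid <- regime_partition(beta, I0, kappa = 0.5, tau = 50)
  list(params = list(kappa = 0.5, tau = 50),
       summary = dplyr::count(tibble::as_tibble(grid), .data$label),
       artifacts = list(regimes = tibble::as_tibble(grid)))
}

exp_tristable_demo <- function(seed, scale, eps = 0.003,
                               target_switches = 100) {
  t_total <- max(1500, target_switches * 40)
  p0 <- tristable_params(I = 0.6, beta = 1, tau = 50, eps = 0,
                         dt = if (scale == "desk") 1e-4 else 1e-6,
                         t_total = 1500, seed = seed)
  sim0 <- simulate_tristable(p0, init = list(u = c(1, 0, 0),
                                             q = c(0.6, 0.8, 1)))
  p1 <- p0; p1$eps <- eps; p1$t_total <- t_total
  sim1 <- simulate_tristable(p1, init = list(u = c(1, 0, 0),
                                             q = c(0.6, 0.8, 1)))
  s0 <- switch_statistics(sim0$records)
  s1 <- switch_statistics(sim1$records)
  list(params = p1[setdiff(names(p1), "seed")],
       summary = tibble::tibble(p_f_noise_free = s0$p_f,
                                p_f_noisy = s1$p_f,
                                eps = eps,
                                n_epochs_noisy = nrow(sim1$records)),
       artifacts = list(dominance_noise_free = sim0$records,
                        dominance_noisy = sim1$records))
}

exp_pf_noise_sweep <- function(seed, scale,
                               eps_grid = c(1e-4, 3e-4, 1e-3, 3e-3),
                               target_switches = 150) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, length(eps_grid))
  t_total <- max(2000, target_switches * 40)
  rows <- purrr::map2_dfr(eps_grid, seeds, function(e, s) {
    p <- tristable_params(I = 0.6, beta = 1, tau = 50, eps = e,
                          dt = if (scale == "desk") 1e-4 else 1e-6,
                          t_total = t_total, seed = s)
    sim <- simulate_tristable(p, init = list(u = c(1, 0, 0),
                                             q = c(0.6, 0.8, 1)))
    st <- switch_statistics(sim$records)
    tibble::tibble(eps = e, p_f = st$p_f,
                   n_switches = st$n_forward + st$n_back, seed = s)
  })
  list(params = list(I = 0.6, beta = 1, tau = 50),
       summary = tibble::tibble(p_f_min = min(rows$p_f),
                                p_f_max = max(rows$p_f)),
       artifacts = list(pf_sweep = rows))
}
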