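#' Pool dominance epochs across independent ring simulations
#'
#' Runs independent replicates of [simulate_ring()] (one RNG seed per
#' replicate) and concatenates their non-censored dominance records
#' until a target number of epochs and/or complete R-L cycles has been
#' collected, or the seed list is exhausted. Pooling independent
#' replicates rather than one very long run keeps memory bounded and
#' parallels how dominance statistics are accumulated experimentally.
#'
#' @param params a [ring_params()] object; its `seed` field is replaced
#'   per replicate.
#' @param seeds integer vector of replicate seeds.
#' @param target_epochs stop once this many epochs are pooled.
#' @param target_cycles stop once this many complete cycles (pairs of
#'   R and L epochs) are pooled.
#' @param init,min_dwell,burn_in passed to [simulate_ring()].
#' @param record_dt recording interval (model units).
#' @return Tibble of pooled records with an extra `replicate` column.
#' @export
pool_ring_epochs <- function(params, seeds, target_epochs = Inf,
                             target_cycles = Inf, init = "wta_right",
                             record_dt = 0.01, min_dwell = 0.5,
                             burn_in = 50) {
  out <- list()
  n_ep <- 0; n_cyc <- 0
  for (k in seq_along(seeds)) {
    p <- params
    p$seed <- seeds[k]
    sim <- simulate_ring(p, init = init, record_dt = record_dt,
                         min_dwell = min_dwell, burn_in = burn_in)
    rec <- sim$records[!sim$records$censored, , drop = FALSE]
    rec$replicate <- k
    out[[k]] <- rec
    n_ep <- n_ep + nrow(rec)
    n_cyc <- n_cyc + min(sum(rec$percept == "R"), sum(rec$percept == "L"))
    if (n_ep >= target_epochs && n_cyc >= target_cycles) break
  }
  dplyr::bind_rows(out)
}
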