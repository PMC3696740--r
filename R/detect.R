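#' Extract dominance epochs from a simulated trajectory
#'
#' Assigns a percept label at every recorded time point and collapses
#' the label series into dominance epochs. For the ring model the
#' percept is decided by comparing the peak activity over the right
#' (\eqn{x > 0}) and left (\eqn{x < 0}) halves of the orientation
#' domain; for the space-free networks by comparing population rates.
#' The comparison is strict: at an exact tie the incumbent percept is
#' retained. A candidate switch must persist for at least `min_dwell`
#' model units before it is logged (a debounce that suppresses
#' double-counting of the threshold crossing under noise); epochs whose
#' onset precedes `burn_in` are discarded, which also removes the
#' (possibly truncated) first epoch inherited from the initial
#' condition. The final epoch is retained but marked `censored`
#' because the run ends before its switch; statistics functions exclude
#' censored epochs.
#'
#' @param trajectory a tibble with a `t` column and either `peak_R` /
#'   `peak_L` columns (ring) or one activity column per population
#'   whose names become the percept labels.
#' @param min_dwell debounce dwell in model units (default 0.5, i.e.
#'   5 ms).
#' @param burn_in initial interval to discard, model units (default 50).
#' @param time_unit_ms milliseconds per model unit.
#' @return Tibble with columns `percept`, `t_on`, `duration`,
#'   `duration_s`, `censored`. Consecutive rows always carry distinct
#'   labels and tile the post-burn-in interval.
#' @export
detect_dominance <- function(trajectory, min_dwell = 0.5, burn_in = 50,
                             time_unit_ms = 10) {
  if (is.null(trajectory) || nrow(trajectory) == 0)
    stop("empty trajectory: nothing to detect dominance on")
  t <- trajectory$t
  if (all(c("peak_R", "peak_L") %in% names(trajectory))) {
    labels <- ifelse(trajectory$peak_R > trajectory$peak_L, "R",
                     ifelse(trajectory$peak_L > trajectory$peak_R, "L",
                            NA_character_))
  } else {
    acts <- as.matrix(trajectory[setdiff(names(trajectory), "t")])
    imax <- max.col(acts, ties.method = "first")
    mx <- acts[cbind(seq_len(nrow(acts)), imax)]
    n_at_max <- rowSums(acts == mx)
    labels <- colnames(acts)[imax]
    labels[n_at_max > 1] <- NA_character_   # ties keep the incumbent
  }
  labels <- locf(labels)
  dominance_epochs(t, labels, min_dwell, burn_in, time_unit_ms)
}

# last-observation-carried-forward for the tie convention
locf <- function(x) {
  i <- seq_along(x)
  i[is.na(x)] <- NA
  x[cummax_na(i)]
}

cummax_na <- function(i) {
  last <- NA_integer_
  for (k in seq_along(i)) {
    if (!is.na(i[k])) last <- i[k] else i[k] <- last
  }
  i
}

# collapse a label series into debounced epochs
dominance_epochs <- function(t, labels, min_dwell, burn_in, time_unit_ms) {
  keep <- !is.na(labels)
  t <- t[keep]; labels <- labels[keep]
  if (!length(t))
    return(tibble::tibble(percept = character(), t_on = double(),
                          duration = double(), duration_s = double(),
                          censored = logical()))
  step <- if (length(t) > 1) t[2] - t[1] else 0
  r <- rle(labels)
  lab <- r$values; len <- r$lengths
  if (min_dwell > 0 && step > 0) {
    min_len <- ceiling(min_dwell / step)
    # absorb, in time order, every run shorter than the dwell into the
    # incumbent (preceding) percept; single left-to-right stack pass,
    # repeated until stable
    repeat {
      k <- length(len)
      if (k <= 1) break
      s_lab <- character(k); s_len <- integer(k); top <- 0L
      for (i in seq_len(k)) {
        if (top > 0L && (len[i] < min_len || lab[i] == s_lab[top])) {
          # absorb flickers and merge adjacent same-label runs
          s_len[top] <- s_len[top] + len[i]
        } else {
          top <- top + 1L
          s_lab[top] <- lab[i]; s_len[top] <- len[i]
        }
      }
      new_lab <- s_lab[seq_len(top)]; new_len <- s_len[seq_len(top)]
      # leading stub belongs to its successor
      while (length(new_len) > 1 && new_len[1] < min_len) {
        new_lab <- new_lab[-1]
        new_len[2] <- new_len[2] + new_len[1]
        new_len <- new_len[-1]
      }
      stable <- identical(new_lab, lab) && identical(new_len, len)
      lab <- new_lab; len <- new_len
      if (stable) break
    }
  }
  ends <- cumsum(len)
  starts <- c(1L, head(ends, -1L) + 1L)
  t_on <- t[starts]
  t_off <- c(t[starts[-1]], t[length(t)] + step)
  out <- tibble::tibble(percept = lab, t_on = t_on,
                        duration = t_off - t_on,
                        censored = c(rep(FALSE, length(lab) - 1), TRUE))
  kept <- out[out$t_on >= burn_in, , drop = FALSE]
  # a run with no post-burn-in switch still yields its single
  # (open-ended) record spanning the simulation
  out <- if (nrow(kept) == 0) out[nrow(out), , drop = FALSE] else kept
  out$duration_s <- to_seconds(out$duration, time_unit_ms)
  out[, c("percept", "t_on", "duration", "duration_s", "censored")]
}

#' Write / read dominance records as CSV
#'
#' The on-disk format has the four columns
#' `percept,t_on,duration,duration_s` (censored epochs are dropped on
#' write).
#'
#' @param records tibble from [detect_dominance()].
#' @param path file path.
#' @return `write_dominance_csv()` returns `path` invisibly;
#'   `read_dominance_csv()` returns the records tibble.
#' @export
write_dominance_csv <- function(records, path) {
  out <- records[!records$censored,
                 c("percept", "t_on", "duration", "duration_s")]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_dominance_csv
#' @export
read_dominance_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    percept = readr::col_character(), t_on = readr::col_double(),
    duration = readr::col_double(), duration_s = readr::col_double()))
}
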