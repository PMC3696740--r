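make_peaks <- function(segments, step = 0.1) {
  # segments: list of c(label_is_R, duration)
  lab <- unlist(lapply(segments, function(s) rep(s[1], round(s[2] / step))))
  tibble::tibble(t = (seq_along(lab) - 1) * step,
                 peak_R = ifelse(lab == 1, 1, 0),
                 peak_L = ifelse(lab == 1, 0, 1))
}

test_that("epochs are extracted with onset, duration and units", {
  pk <- make_peaks(list(c(1, 30), c(0, 20), c(1, 25)))
  rec <- detect_dominance(pk, min_dwell = 0.5, burn_in = 0)
  expect_equal(rec$percept, c("R", "L", "R"))
  expect_equal(rec$duration, c(30, 20, 25), tolerance = 1e-8)
  expect_equal(rec$duration_s, rec$duration * 10 / 1000)
  expect_equal(rec$censored, c(FALSE, FALSE, TRUE))
  # records tile the interval
  expect_equal(sum(rec$duration), 75, tolerance = 1e-8)
  expect_equal(rec$t_on[-1], rec$t_on[-3] + rec$duration[-3],
               tolerance = 1e-8)
})

test_that("flickers shorter than the dwell are absorbed by the incumbent", {
  pk <- make_peaks(list(c(1, 30), c(0, 0.3), c(1, 10), c(0, 20)))
  rec <- detect_dominance(pk, min_dwell = 0.5, burn_in = 0)
  expect_equal(rec$percept, c("R", "L"))
  expect_equal(rec$duration[1], 40.3, tolerance = 1e-8)
  # the same flicker is kept when it exceeds the dwell
  pk2 <- make_peaks(list(c(1, 30), c(0, 0.7), c(1, 10), c(0, 20)))
  rec2 <- detect_dominance(pk2, min_dwell = 0.5, burn_in = 0)
  expect_equal(rec2$percept, c("R", "L", "R", "L"))
})

test_that("exact ties retain the incumbent percept", {
  pk <- make_peaks(list(c(1, 10), c(0, 10)))
  pk$peak_L[30:40] <- pk$peak_R[30:40]   # tie inside the L epoch?
  pk2 <- make_peaks(list(c(1, 10), c(0, 10)))
  pk2$peak_L[50:60] <- 1; pk2$peak_R[50:60] <- 1  # tie plateau
  rec <- detect_dominance(pk2, min_dwell = 0.5, burn_in = 0)
  expect_equal(rec$percept, c("R", "L"))
})

test_that("a run without switches yields one censored record", {
  pk <- make_peaks(list(c(1, 100)))
  rec <- detect_dominance(pk, burn_in = 20)
  expect_equal(nrow(rec), 1L)
  expect_true(rec$censored)
  expect_equal(rec$percept, "R")
})

test_that("burn-in drops the initial truncated epoch", {
  pk <- make_peaks(list(c(1, 60), c(0, 30), c(1, 30)))
  rec <- detect_dominance(pk, burn_in = 50)
  # the R epoch straddling t = 50 is discarded
  expect_equal(rec$percept, c("L", "R"))
  expect_gte(min(rec$t_on), 50)
})

test_that("empty trajectories are rejected", {
  expect_error(detect_dominance(tibble::tibble()), "empty")
})

test_that("dominance CSV round-trips", {
  pk <- make_peaks(list(c(1, 30), c(0, 20), c(1, 25)))
  rec <- detect_dominance(pk, burn_in = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dominance_csv(rec, path)
  expect_equal(readLines(path, n = 1), "percept,t_on,duration,duration_s")
  back <- read_dominance_csv(path)
  expect_equal(back$duration, rec$duration[!rec$censored])
})
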