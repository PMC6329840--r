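# independent brute-force helpers used as oracles -----------------------------

# run-length scan without rle()
scan_runs <- function(exceed, min_len) {
  out <- NULL
  i <- 1
  while (i <= length(exceed)) {
    if (exceed[i]) {
      j <- i
      while (j < length(exceed) && exceed[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len)
        out <- rbind(out, c(start = i, end = j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# straightforward HWMId re-implementation (day-by-day loop)
hwmid_oracle <- function(series, thr, t25, t75, min_len = 3) {
  if (t75 <= t25) return(0)
  runs <- scan_runs(series > thr, min_len)
  if (is.null(runs)) return(0)
  best <- 0
  for (r in seq_len(nrow(runs))) {
    m <- 0
    for (d in runs[r, 1]:runs[r, 2]) {
      md <- (series[d] - t25) / (t75 - t25)
      m <- m + max(0, md)
    }
    best <- max(best, m)
  }
  best
}

test_that("threshold climatology matches the percentile rule and is equivariant", {
  # constant reference -> constant thresholds
  const <- matrix(20, 365, 12)
  expect_equal(compute_thresholds(const), rep(20, 365))

  # window = 1, day-d values 1..10 across 10 reference years:
  # threshold = type-7 90th percentile of {1..10}
  ref <- matrix(rep(1:10, each = 365), 365, 10)
  thr <- compute_thresholds(ref, window = 1)
  expect_equal(thr, rep(unname(quantile(1:10, 0.9, type = 7)), 365))

  # thresholds equal stats::quantile on the pooled 31-day window
  set.seed(3)
  x <- matrix(rnorm(365 * 12, 15, 4), 365, 12)
  thr <- compute_thresholds(x)
  for (d in c(1, 100, 365)) {
    idx <- (((d - 15):(d + 15)) - 1) %% 365 + 1
    expect_equal(thr[d], unname(quantile(x[idx, ], 0.9, type = 7)))
  }

  # shifting the whole series shifts every threshold by the same constant
  expect_equal(compute_thresholds(x + 2), thr + 2)
})

test_that("heatwave detection requires three consecutive exceedance days", {
  thr <- rep(25, 365)
  s <- flat_year()
  s[50:51] <- 30                       # only two consecutive days
  expect_equal(nrow(detect_heatwaves(s, thr)), 0L)

  s <- flat_year(); s[100:104] <- 30   # five days -> one event
  ev <- detect_heatwaves(s, thr)
  expect_equal(ev, data.frame(start = 100L, end = 104L, duration = 5L))

  s <- flat_year(); s[10:12] <- 30; s[20:23] <- 30
  ev <- detect_heatwaves(s, thr)
  expect_equal(ev$duration, c(3L, 4L))
  expect_equal(ev$start, c(10L, 20L))
})

test_that("detected events match a brute-force run scan on random patterns", {
  set.seed(11)
  thr <- rep(0, 365)
  for (r in 1:25) {
    s <- rnorm(365)
    ev <- detect_heatwaves(s, thr)
    runs <- scan_runs(s > thr, 3)
    if (is.null(runs)) {
      expect_equal(nrow(ev), 0L)
    } else {
      expect_equal(ev$start, unname(runs[, "start"]))
      expect_equal(ev$end, unname(runs[, "end"]))
    }
    # events partition the exceedance days belonging to runs >= 3
    ev_days <- unlist(Map(seq, ev$start, ev$end))
    run_days <- unlist(Map(seq, runs[, "start"], runs[, "end"]))
    expect_setequal(ev_days, run_days)
  }
})

test_that("HWMId handles the no-event, scaling-identity and degenerate cases", {
  thr <- rep(25, 365)
  expect_equal(hwmid_annual(flat_year(), thr, 20, 24), 0)

  # a 3-day heatwave sitting exactly at T75p scores 1 per day
  s <- flat_year(); s[200:202] <- 24
  expect_equal(hwmid_annual(s, thr - 5, t25 = 20, t75 = 24), 3)

  # degenerate reference quartiles give 0, not a division by zero
  expect_equal(as.numeric(hwmid_annual(s, thr - 5, 22, 22)), 0)
})

test_that("HWMId equals an independent brute-force re-implementation", {
  set.seed(21)
  worst <- 0
  for (r in 1:100) {
    s <- 20 + 5 * sin(2 * pi * (1:365) / 365) + rnorm(365, sd = 3)
    thr <- 20 + 5 * sin(2 * pi * (1:365) / 365) + runif(1, 0.5, 2)
    t25 <- runif(1, 22, 25); t75 <- t25 + runif(1, 0.5, 4)
    worst <- max(worst, abs(hwmid_annual(s, thr, t25, t75) -
                              hwmid_oracle(s, thr, t25, t75)))
  }
  expect_lt(worst, 1e-9)
})

test_that("HWMId is invariant under a common shift of series and reference", {
  set.seed(5)
  s <- 20 + rnorm(365, sd = 4)
  thr <- rep(21, 365)
  h0 <- hwmid_annual(s, thr, 24, 28)
  h1 <- hwmid_annual(s + 3, thr + 3, 24 + 3, 28 + 3)
  expect_equal(h1, h0)
  expect_gte(h0, 0)
})

test_that("TX5x equals the sliding-window oracle and respects its bounds", {
  expect_equal(tx5x_annual(rep(30, 365)), 30)
  lin <- seq_len(365) * 0.1
  expect_equal(tx5x_annual(lin), mean(lin[361:365]))
  expect_error(tx5x_annual(1:4), "shorter")

  set.seed(8)
  for (r in 1:20) {
    s <- rnorm(365, 20, 5)
    oracle <- max(vapply(1:361, function(i) mean(s[i:(i + 4)]), numeric(1)))
    v <- tx5x_annual(s)
    expect_equal(v, oracle)
    expect_lte(v, max(s))
    expect_gte(v, mean(vapply(1:361, function(i) mean(s[i:(i + 4)]),
                              numeric(1))))
  }
})

test_that("annual index series wraps cells and years consistently", {
  cfg <- tiny_world(nlat = 2, nlon = 2, years = 20)
  x <- generate_climate(cfg, "present")
  thr <- compute_thresholds(x)
  q <- reference_quartiles(x)
  hw <- annual_index_series(x, thr, q, "hwmid")
  expect_equal(dim(hw), c(20, 4))
  expect_true(all(hw >= 0))
  expect_equal(hw[3, 2],
               hwmid_annual(x[, 3, 2], thr[, 2], q$t25[2], q$t75[2]))
  tx <- annual_index_series(x, thr, index = "tx5x")
  expect_equal(tx[5, 4], tx5x_annual(x[, 5, 4]))
})
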