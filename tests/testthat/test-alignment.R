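# alignment module: lag recovery, oracle equivalence, window extraction.

# Hann burst of given onset (samples) in a series of length n
burst_series <- function(n, onset, blen = 300, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n) + if (noise > 0) rnorm(n, 0, noise) else 0
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(blen) - 1) / (blen - 1))
  idx <- onset + seq_len(blen)
  keep <- idx >= 1 & idx <= n
  x[idx[keep]] <- x[idx[keep]] + w[keep]
  x
}

test_that("identical series align at lag zero", {
  g <- burst_series(2000, 500, noise = 0.01, seed = 1)
  lags <- align_iterations(list(g, g, g), rate = 200, max_lag_ms = 2000)
  expect_equal(as.vector(lags), c(0, 0, 0))
  expect_equal(attr(lags, "reference"), 1L)
})

test_that("a delayed response is recovered as a positive lag", {
  # iteration 2's burst occurs 500 ms later (100 samples at 200 Hz):
  # positive lag, so its window shifts later by the same amount
  a <- burst_series(2000, 500, noise = 0.005, seed = 2)
  b <- burst_series(2000, 600, noise = 0.005, seed = 3)
  lags <- align_iterations(list(a, b), rate = 200, smooth_ms = 0)
  expect_equal(lags[2], 500, tolerance = 0.021)
  # and the direct engine agrees exactly
  lags_d <- align_iterations(list(a, b), rate = 200, smooth_ms = 0,
                             engine = "direct")
  expect_identical(lags, lags_d)
})

test_that("fewer than two usable iterations drops the action", {
  g <- burst_series(1000, 200)
  expect_error(align_iterations(list(g, NULL, NULL), rate = 200),
               class = "infasym_too_few_iterations")
})

test_that("fast and brute-force lag search agree exactly", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(300:2000, 1)
    max_lag <- sample(50:150, 1)
    a <- burst_series(n, sample(n %/% 2, 1), blen = 200, noise = 0.3)
    b <- burst_series(n, sample(n %/% 2, 1), blen = 200, noise = 0.3)
    cf <- infasym:::.xcorr_lags_fft(a, b, max_lag)
    cd <- xcorr_lags_direct(a, b, max_lag)
    expect_equal(cf, cd, tolerance = 1e-9)
    expect_identical(which.max(cf), which.max(cd))
    # with random masks
    va <- runif(n) > 0.05; vb <- runif(n) > 0.05
    cf2 <- infasym:::.xcorr_lags_fft(a, b, max_lag, va, vb)
    cd2 <- xcorr_lags_direct(a, b, max_lag, va, vb)
    expect_equal(cf2, cd2, tolerance = 1e-9)
    expect_identical(which.max(cf2), which.max(cd2))
  }
})

test_that("alignment is shift-equivariant", {
  base <- lapply(c(400, 470, 520), function(on)
    burst_series(2000, on, noise = 0.01, seed = on))
  lags0 <- align_iterations(base, rate = 200)
  shifted <- lapply(c(400, 470, 520) + 80, function(on)
    burst_series(2000, on, noise = 0.01, seed = on - 80))
  lags1 <- align_iterations(shifted, rate = 200)
  expect_equal(unname(lags1 - lags1[1]), unname(lags0 - lags0[1]),
               tolerance = 1e-12)
})

test_that("window extraction follows delay, lag, clamping and masks", {
  rate <- 200; n <- 10 * rate
  const <- make_envelope(rep(2, n), rep(2, n), rate = rate)
  for (lag in c(-400, 0, 1200)) {
    w <- extract_window(const, lag)
    expect_equal(c(w$mean_left, w$mean_right), c(2, 2))
  }

  # indicator envelope on [2000, 7000) ms
  ind <- numeric(n); ind[(2000 / 1000 * rate + 1):(7000 / 1000 * rate)] <- 1
  env <- make_envelope(ind, ind, rate = rate)
  w0 <- extract_window(env, 0)
  expect_equal(c(w0$mean_left, w0$mean_right), c(1, 1))
  expect_false(w0$clamped)

  # lag +4000 ms clamps the window to [6000, 10000); the 5% edge trim
  # further restricts means to [6000, 9500): 1000 ms of ones / 3500 ms
  w4 <- extract_window(env, 4000)
  expect_true(w4$clamped)
  expect_equal(w4$mean_left, 1000 / 3500, tolerance = 1e-6)

  # window >50% masked -> iteration excluded
  mk <- rep(FALSE, n); mk[(2.5 * rate):(6.5 * rate)] <- TRUE
  wmask <- extract_window(make_envelope(ind, ind, rate = rate, mask = mk), 0)
  expect_true(wmask$excluded)
})

test_that("average_action keeps >= 2 iterations and averages them", {
  w <- function(l, r) list(mean_left = l, mean_right = r, excluded = FALSE)
  act <- average_action(list(w(2, 4), w(4, 2)), action_id = 3L)
  expect_equal(c(act$mean_left, act$mean_right), c(3, 3))
  expect_equal(act$n_iterations_used, 2L)

  expect_null(average_action(list(w(2, 4))))
  excl <- list(mean_left = NA_real_, mean_right = NA_real_, excluded = TRUE)
  expect_null(average_action(list(w(2, 4), excl)))

  same <- average_action(rep(list(w(1.5, 2.5)), 4))
  expect_equal(c(same$mean_left, same$mean_right), c(1.5, 2.5))
})
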