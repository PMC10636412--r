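# preprocess module: filters, re-reference, bad channels, segmentation,
# amplitude artifacts.

test_that("notch filter kills 60 Hz and spares the passband", {
  rec60 <- sine_recording(60, amp = 10, rate = 1000, dur_s = 4)
  out <- notch_filter(rec60)
  expect_lt(sqrt(mean(interior(out$data[1, ])^2)), 1)      # RMS <= 1 uV

  rec8 <- sine_recording(8, amp = 10, rate = 1000, dur_s = 4)
  out8 <- notch_filter(rec8)
  amp8 <- max(abs(interior(out8$data[1, ])))
  expect_lt(abs(amp8 - 10) / 10, 0.05)

  z <- make_recording(matrix(0, 2, 1000), rate = 1000)
  expect_equal(notch_filter(z)$data, z$data)
  expect_error(notch_filter(make_recording(matrix(0, 1, 100), rate = 100)),
               "too low")
})

test_that("band-pass matches the analytic Butterworth response", {
  # zero-phase application squares the magnitude response; the surviving
  # component amplitude is measured by projection onto the input sinusoid,
  # which is insensitive to broadband padding leakage
  rate <- 1000; dur <- 6
  t <- (seq_len(rate * dur) - 1L) / rate
  for (freq in c(8, 200)) {
    rec <- sine_recording(freq, amp = 1, rate = rate, dur_s = dur)
    out <- bandpass_filter(rec, 0.3, 40, 1L)
    ref <- sin(2 * pi * freq * t)
    got <- 2 * mean(interior(out$data[1, ], 0.2) * interior(ref, 0.2))
    want <- butter_bandpass_gain(freq, 0.3, 40, 1L)^2
    expect_lt(abs(got - want) / want, 0.02)
  }
  # constant input is fully rejected
  dc <- make_recording(matrix(100, 2, 4000), rate = 1000)
  expect_lt(max(abs(interior(bandpass_filter(dc)$data[1, ]))), 1)
  expect_error(bandpass_filter(sine_recording(8, rate = 100), 50, 40),
               "invalid band")
})

test_that("filter chain is linear (additivity)", {
  set.seed(4)
  a <- matrix(rnorm(2 * 2000), 2)
  b <- matrix(rnorm(2 * 2000), 2)
  fa <- bandpass_filter(make_recording(a, rate = 500))$data
  fb <- bandpass_filter(make_recording(b, rate = 500))$data
  fab <- bandpass_filter(make_recording(a + b, rate = 500))$data
  expect_lt(max(abs(fab - (fa + fb))) / max(abs(fab)), 1e-6)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  toy <- make_recording(matrix(c(3, 1), 2, 10), rate = 100)
  out <- rereference_average(toy)
  expect_equal(unname(out$data[, 1]), c(1, -1))
  expect_equal(out$reference, "average")

  set.seed(5)
  rec <- make_recording(matrix(rnorm(6 * 100), 6), rate = 100)
  r1 <- rereference_average(rec)
  expect_lt(max(abs(colMeans(r1$data))), 1e-9)
  r2 <- rereference_average(r1)
  expect_equal(r2$data, r1$data)

  # bad channels excluded from the mean
  recb <- make_recording(rbind(rec$data, 500), rate = 100, bad = "E7")
  rb <- rereference_average(recb)
  expect_lt(max(abs(colMeans(rb$data[1:6, ]))), 1e-9)

  allbad <- make_recording(matrix(0, 2, 5), rate = 100, bad = c("E1", "E2"))
  expect_error(rereference_average(allbad), "all channels")
})

test_that("bad-channel detection flags flat and extreme channels", {
  set.seed(6)
  data <- matrix(rnorm(4 * 1000, sd = 10), 4)
  data[2, ] <- 0.001 * rnorm(1000)              # flat
  data[3, ] <- 500 * sign(sin(seq_len(1000)))   # railed
  rec <- make_recording(data, rate = 200)
  bad <- detect_bad_channels(rec)
  expect_setequal(bad, c("E2", "E3"))
})

test_that("interpolation replaces bad channels by neighbour means", {
  m <- test_montage(30)
  n <- 50
  data <- matrix(5, length(m$labels), n)
  rownames(data) <- m$labels
  b <- setdiff(m$labels, c(m$left, m$right))[1]
  data[b, ] <- 999
  rec <- new_recording(data, 200, m$labels)
  out <- interpolate_channels(rec, b, m)
  expect_equal(unname(out$data[b, ]), rep(5, n))    # mean of constant 5s
  untouched <- setdiff(m$labels, b)
  expect_equal(out$data[untouched, ], rec$data[untouched, ])

  expect_identical(interpolate_channels(rec, character(), m), rec)
  expect_error(interpolate_channels(rec, m$labels[1:20], m, max_bad = 19),
               class = "infasym_too_many_bad")
})

test_that("segmentation yields 16 epochs of exact length, 4 per action", {
  m <- test_montage()
  ses <- generate_session(test_params(seed = 13L), m)
  eps <- segment_epochs(ses$recording, ses$schedule)
  expect_length(eps, 16L)
  expect_equal(as.vector(table(vapply(eps, `[[`, 0L, "action_id"))),
               rep(4L, 4L))
  expect_true(all(vapply(eps, function(e) ncol(e$data), 0L) == 10 * 200))
  expect_true(all(vapply(eps, `[[`, TRUE, "usable")))

  # an event too close to end-of-file gives an unusable epoch
  rec <- ses$recording
  short <- new_schedule(data.frame(onset_sample = n_samples(rec) - 5 * 200,
                                   action_id = 1L, iteration = 1L,
                                   run = 1L, trial = 1L), rate = 200)
  ep <- segment_epochs(rec, short)[[1]]
  expect_false(ep$usable)
  expect_match(ep$reason, "truncated")

  # counts invariant under channel permutation
  perm <- sample(nrow(rec$data))
  rec2 <- new_recording(rec$data[perm, ], rec$rate, rec$labels[perm])
  eps2 <- segment_epochs(rec2, ses$schedule)
  expect_equal(vapply(eps2, `[[`, 0L, "action_id"),
               vapply(eps, `[[`, 0L, "action_id"))
})

test_that("amplitude artifact elimination masks with a 100-ms guard", {
  m <- test_montage(30)
  rate <- 200
  data <- matrix(0, length(m$labels), 10 * rate)
  rownames(data) <- m$labels
  ep <- make_epoch(data, rate = rate, labels = m$labels)
  clean <- eliminate_amplitude_artifacts(ep, m)
  expect_equal(clean$masked_fraction, 0)

  # 300-ms, 200-uV artifact on one cluster channel in the epoch interior:
  # 300 ms + 2 x 100 ms pad = 500 ms of 10 s = 0.05
  data2 <- data
  data2[m$left[1], 1000 + seq_len(60)] <- 200
  ep2 <- make_epoch(data2, rate = rate, labels = m$labels)
  out2 <- eliminate_amplitude_artifacts(ep2, m)
  expect_equal(out2$masked_fraction, 0.05)
  expect_true(out2$usable)

  # railed epoch -> fully masked, unusable
  data3 <- data; data3[m$right[3], ] <- 500
  ep3 <- make_epoch(data3, rate = rate, labels = m$labels)
  out3 <- eliminate_amplitude_artifacts(ep3, m)
  expect_equal(out3$masked_fraction, 1)
  expect_false(out3$usable)

  # artifacts outside the clusters are invisible at cluster scope
  data4 <- data
  data4[setdiff(m$labels, c(m$left, m$right))[1], 500:560] <- 400
  out4 <- eliminate_amplitude_artifacts(
    make_epoch(data4, rate = rate, labels = m$labels), m)
  expect_equal(out4$masked_fraction, 0)
  out4all <- eliminate_amplitude_artifacts(
    make_epoch(data4, rate = rate, labels = m$labels), m, scope = "all")
  expect_gt(out4all$masked_fraction, 0)
})
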