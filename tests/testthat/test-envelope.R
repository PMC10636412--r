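# envelope module: alpha band, cluster means, Hilbert envelope, GFP.

test_that("alpha filter passes 7.5 Hz and rejects 3 and 20 Hz", {
  rate <- 200
  t <- (seq_len(10 * rate) - 1L) / rate
  mk <- function(freq) make_epoch(matrix(sin(2 * pi * freq * t), 1),
                                  rate = rate)
  in_band <- alpha_filter(mk(7.5))
  expect_lt(abs(max(abs(interior(in_band$data[1, ]))) - 1), 0.05)
  for (freq in c(3, 20)) {
    out_band <- alpha_filter(mk(freq))
    expect_lt(max(abs(interior(out_band$data[1, ]))), 0.1)
  }
  z <- alpha_filter(make_epoch(matrix(0, 1, 2000)))
  expect_equal(max(abs(z$data)), 0)
  expect_error(alpha_filter(mk(7.5), 9, 6), "invalid")
})

test_that("cluster averages are plain channel means over 7 labels", {
  m <- test_montage(30)
  n <- 100
  data <- matrix(0, length(m$labels), n)
  rownames(data) <- m$labels
  data[m$left, ] <- 3
  ep <- make_epoch(data, labels = m$labels)
  cl <- cluster_average(ep, m)
  expect_equal(cl$left, rep(3, n))
  expect_equal(cl$right, rep(0, n))

  data[m$right[1], ] <- 7
  cl2 <- cluster_average(make_epoch(data, labels = m$labels), m)
  expect_equal(cl2$right, rep(1, n))     # one 7 among six 0s

  m6 <- m; m6$left <- m$left[1:6]
  expect_error(cluster_average(ep, m6), "exactly 7")
  mmiss <- m; mmiss$right[1] <- "NOPE"
  expect_error(cluster_average(ep, mmiss), "absent.*NOPE")
})

test_that("Hilbert envelope recovers amplitude and modulation", {
  rate <- 200
  t <- (seq_len(10 * rate) - 1L) / rate
  env <- hilbert_envelope(3 * sin(2 * pi * 7.5 * t))
  expect_lt(max(abs(interior(env, 0.05) - 3)) / 3, 0.02)

  # slow Hann modulator is tracked within 3%
  mod <- 0.2 + .8 * (0.5 - 0.5 * cos(2 * pi * t / 10))
  env2 <- hilbert_envelope(mod * sin(2 * pi * 7.5 * t))
  rel <- abs(interior(env2, 0.05) - interior(mod, 0.05)) /
    interior(mod, 0.05)
  expect_lt(max(rel), 0.03)

  expect_equal(hilbert_envelope(numeric(100)), numeric(100))
  # sign-flip invariance
  x <- sin(2 * pi * 8 * t) * mod
  expect_equal(hilbert_envelope(-x), hilbert_envelope(x))
  expect_error(hilbert_envelope(rep(NA_real_, 10)), "mask|NA")
})

test_that("GFP is the per-sample population SD across channels", {
  # two channels +a / -a -> gfp = a
  a <- abs(sin(seq(0, 3, length.out = 120))) + 0.2
  ep <- make_epoch(rbind(a, -a))
  expect_equal(global_field_power(ep), a)

  # all channels equal after average reference -> zero field power
  ep0 <- make_epoch(matrix(0, 4, 50))
  expect_equal(global_field_power(ep0), rep(0, 50))

  # permutation invariance and common-offset-plus-rereference invariance
  set.seed(8)
  data <- matrix(rnorm(6 * 200), 6)
  ep1 <- make_epoch(data)
  g1 <- global_field_power(ep1)
  perm <- sample(6)
  expect_equal(global_field_power(make_epoch(data[perm, ])), g1)
  rec <- rereference_average(make_recording(data + 42, rate = 200))
  expect_equal(global_field_power(make_epoch(rec$data)), g1)

  expect_error(global_field_power(make_epoch(matrix(0, 1, 10))),
               "2 good channels")
})

test_that("envelope of cluster mean <= mean of channel envelopes", {
  rate <- 200
  t <- (seq_len(4 * rate) - 1L) / rate
  for (s in 1:5) {
    set.seed(s)
    chans <- vapply(1:7, function(i)
      runif(1, 0.5, 2) * sin(2 * pi * runif(1, 6, 9) * t + runif(1, 0, 7)),
      numeric(length(t)))
    env_mean <- hilbert_envelope(rowMeans(chans))
    mean_env <- rowMeans(apply(chans, 2, hilbert_envelope))
    expect_true(all(env_mean <= mean_env + 1e-8))
  }
})

test_that("GFP peak sits at the injected burst centre", {
  m <- test_montage(30)
  p <- test_params(jitter_sd = 0, artifact_rate = 0, n_bad_channels = 0L,
                   noise_sd = 2, seed = 17L)
  ses <- generate_session(p, m)
  cfg <- default_config()
  rec <- rereference_average(bandpass_filter(notch_filter(ses$recording)))
  eps <- segment_epochs(rec, ses$schedule)
  ep <- alpha_filter(eps[[1]])
  gfp <- global_field_power(ep)
  sm <- stats::filter(gfp, rep(1 / 27, 27), sides = 2)  # ~135 ms MA
  peak_ms <- (which.max(sm) - 1) / ep$rate * 1000
  centre_ms <- 2000 + p$burst_ms / 2       # delay + half burst, no jitter
  expect_lt(abs(peak_ms - centre_ms), 100)
})
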