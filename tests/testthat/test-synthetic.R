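# synthetic_data module: schedule arithmetic, determinism, ground truth.

test_that("build_schedule produces the full paradigm", {
  sched <- build_schedule(test_params())
  expect_s3_class(sched, "event_schedule")
  expect_equal(nrow(sched), 16L)
  expect_equal(as.vector(table(sched$action_id)), rep(4L, 4L))
  # each (action, iteration) pair exactly once
  expect_equal(nrow(unique(sched[c("action_id", "iteration")])), 16L)
  # consecutive onsets within a run 25 s apart (10 s action + 15 s pause)
  rate <- attr(sched, "rate")
  for (r in 1:2) {
    on <- sort(sched$onset_sample[sched$run == r])
    expect_equal(diff(on), rep(25 * rate, 7L))
  }
  # inter-run gap: 2-min break after the last epoch of run 1
  gap <- min(sched$onset_sample[sched$run == 2]) -
    (max(sched$onset_sample[sched$run == 1]) + 10 * rate)
  expect_equal(gap, 120 * rate)
})

test_that("generate_session is deterministic and respects parameters", {
  p <- test_params(seed = 42L)
  m <- test_montage()
  s1 <- generate_session(p, m)
  s2 <- generate_session(p, m)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$schedule), as.data.frame(s2$schedule))

  # no jitter -> identical injected lags across iterations of an action
  s0 <- generate_session(test_params(jitter_sd = 0, seed = 3L), m)
  expect_true(all(apply(s0$truth$true_lags_ms, 1L,
                        function(r) diff(range(r)) == 0)))
  expect_equal(unname(s0$truth$true_lags_ms[1, 1]), 2000)

  # bad channels recorded and outside the clusters
  expect_length(s1$truth$bad_channel_labels, p$n_bad_channels)
  expect_length(intersect(s1$truth$bad_channel_labels,
                          c(m$left, m$right)), 0L)

  # no artifacts requested -> none recorded
  s3 <- generate_session(test_params(artifact_rate = 0, seed = 5L), m)
  expect_length(s3$truth$artifact_times, 0L)
})

test_that("sim_params rejects invalid configurations", {
  expect_error(test_params(asymmetry_per_action = c(0, 0, 0)), "exactly 4")
  expect_error(test_params(sample_rate = 60), "80 Hz")
  expect_error(test_params(jitter_sd = -1), "jitter_sd")
  expect_error(test_params(alpha_freq = 11), "6, 9")
  expect_error(test_params(drowsy_iteration_prob = 1.5), "0, 1")
  expect_error(test_params(asymmetry_per_action = c(0, 0, 0, 2)), "-1, 1")
})

test_that("generate_wecs: states, drowsy rule, determinism", {
  p <- test_params(seed = 11L)
  w1 <- generate_wecs(p, list(ok = TRUE))
  w2 <- generate_wecs(p, list(ok = TRUE))
  expect_identical(w1, w2)
  expect_equal(nrow(w1), 4 * 4 * 3)
  expect_true(all(w1$score[w1$state != "drowsy"] %in% 1:3))

  # markedly drowsy -> sensitivity coded 0
  wd <- generate_wecs(test_params(drowsy_iteration_prob = 1, seed = 2L),
                      list(ok = TRUE))
  expect_true(all(wd$score[wd$domain == "sensitivity"] == 0L))
  expect_true(all(wd$state == "drowsy"))

  # non-irritable infants are never inconsolable; irritable ones can be
  expect_false(any(w1$state == "inconsolable"))
})

test_that("null wecs_effect gives a flat trend; 0.4 a positive one", {
  dummy <- list(ok = TRUE)
  slope_of <- function(w) unname(coef(lm(score ~ action,
                                         data = w[w$score > 0, ]))[2])
  null_slopes <- vapply(1:100, function(s)
    slope_of(generate_wecs(test_params(wecs_effect = 0, seed = s), dummy)),
    numeric(1))
  ci <- mean(null_slopes) +
    c(-1, 1) * stats::qt(0.995, 99) * sd(null_slopes) / 10
  expect_true(ci[1] < 0 && ci[2] > 0)

  pos <- vapply(1:100, function(s)
    slope_of(generate_wecs(test_params(wecs_effect = 0.4, seed = 200 + s),
                           dummy)) > 0, logical(1))
  expect_gte(sum(pos), 95L)
})

test_that("conservation: zero asymmetry leaves clusters balanced", {
  m <- test_montage()
  d <- lvl <- c()
  for (s in c(9L, 10L, 11L)) {
    p <- test_params(asymmetry_per_action = rep(0, 4), artifact_rate = 0,
                     n_bad_channels = 0L, seed = s)
    ses <- generate_session(p, m)
    res <- analyze_session(ses$recording, ses$schedule, m,
                           default_config())
    d <- c(d, res$mean_left - res$mean_right)
    lvl <- c(lvl, (res$mean_left + res$mean_right) / 2)
  }
  # pooled left-right window-mean differences are centred on zero within
  # 3 SEs of their own spread, and small relative to the envelope level
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  expect_lt(max(abs(d)) / mean(lvl), 0.1)
})

test_that("generate_meta is consistent with the irritability rule", {
  p_irr <- test_params(irritable = TRUE, seed = 21L)
  w <- generate_wecs(p_irr, list(ok = TRUE))
  meta <- generate_meta(p_irr, w)
  expect_true(classify_irritability(meta))

  p_ok <- test_params(irritable = FALSE, seed = 22L)
  w2 <- generate_wecs(p_ok, list(ok = TRUE))
  meta2 <- generate_meta(p_ok, w2)
  expect_false(classify_irritability(meta2))
  expect_true(meta2$mibs >= 0 && meta2$mibs <= 24)
  expect_true(meta2$epds >= 0 && meta2$epds <= 30)
})

test_that("simulate_cohort varies irritability and stays reproducible", {
  c1 <- simulate_cohort(3, test_params(), seed = 7L)
  c2 <- simulate_cohort(3, test_params(), seed = 7L)
  expect_identical(lapply(c1, `[[`, "meta"), lapply(c2, `[[`, "meta"))
  expect_identical(c1[[2]]$recording$data, c2[[2]]$recording$data)
  ids <- vapply(c1, function(d) d$meta$infant_id, "")
  expect_equal(ids, c("S01", "S02", "S03"))
})
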