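# Synthetic dyad sessions with analytic ground truth.
#
# The generator emulates what the analysis pipeline expects from a real
# session: a high-density vertex-referenced recording containing lateralized
# alpha-band bursts time-locked (with jitter) to scripted maternal actions,
# broadband background noise, blink-like high-amplitude artifacts, dead or
# railed channels, plus behaviourally coded responsiveness scores and dyad
# questionnaire metadata. All injected quantities are returned as ground
# truth so recovery can be asserted exactly.

#' Simulation parameters
#'
#' Defaults describe the recording and paradigm as specified for the study
#' design this package targets: 128 channels at 1000 Hz, infant alpha at the
#' centre of the 6-9 Hz band, a 2000-ms mean response delay after action
#' onset, and a negative-to-positive asymmetry progression across the four
#' actions (the pattern reported for non-irritable infants). Background noise
#' and artifact rates are set to values typical of awake infant EEG.
#'
#' @param n_channels number of electrodes (14..128; the 14 frontal-cluster
#'   channels are always included).
#' @param sample_rate Hz; must exceed 80 Hz (2 x the 40 Hz band edge).
#' @param asymmetry_per_action four signed effect sizes in `[-1, 1]`: the
#'   relative left-vs-right alpha burst amplitude difference per action.
#'   With left amplitude `A(1+a)` and right `A(1-a)`, the noiseless frontal
#'   asymmetry score equals `a`.
#' @param jitter_sd SD (ms) of the per-iteration response-onset jitter.
#' @param response_delay_mean mean infant response delay after action onset
#'   (ms).
#' @param alpha_freq burst frequency, Hz, within 6-9.
#' @param noise_sd background noise SD per channel (microvolts); an equal mix
#'   of white and 1/f ("pink") noise.
#' @param artifact_rate blink-like artifact events per minute, amplitude
#'   150-300 microvolts on frontal channels.
#' @param n_bad_channels number of flat or railed channels (chosen outside
#'   the frontal clusters so envelope ground truth stays analytic).
#' @param drowsy_iteration_prob probability an iteration is coded drowsy.
#' @param wecs_effect latent-scale increase of behavioural scores per action
#'   index when `irritable = FALSE` (flat when `TRUE`).
#' @param irritable logical: simulate an irritable infant (flat behavioural
#'   and neural progression, consoling events, possible inconsolable
#'   iterations).
#' @param alpha_amp peak alpha burst amplitude before lateralization
#'   (microvolts).
#' @param burst_ms burst duration (ms), 3000-8000.
#' @param seed integer RNG seed; every generated artefact is a deterministic
#'   function of the parameter set including the seed.
#' @return validated `sim_params` list.
#' @export
sim_params <- function(n_channels = 128L,
                       sample_rate = 1000,
                       asymmetry_per_action = c(-0.15, -0.05, 0.15, 0.25),
                       jitter_sd = 300,
                       response_delay_mean = 2000,
                       alpha_freq = 7.5,
                       noise_sd = 10,
                       artifact_rate = 2,
                       n_bad_channels = 3L,
                       drowsy_iteration_prob = 0.02,
                       wecs_effect = 0.4,
                       irritable = FALSE,
                       alpha_amp = 15,
                       burst_ms = 5000,
                       seed = 1L) {
  p <- list(n_channels = as.integer(n_channels), sample_rate = sample_rate,
            asymmetry_per_action = asymmetry_per_action,
            jitter_sd = jitter_sd,
            response_delay_mean = response_delay_mean,
            alpha_freq = alpha_freq, noise_sd = noise_sd,
            artifact_rate = artifact_rate,
            n_bad_channels = as.integer(n_bad_channels),
            drowsy_iteration_prob = drowsy_iteration_prob,
            wecs_effect = wecs_effect, irritable = isTRUE(irritable),
            alpha_amp = alpha_amp, burst_ms = burst_ms,
            seed = as.integer(seed))
  if (length(p$asymmetry_per_action) != 4L)
    stop("asymmetry_per_action must have exactly 4 entries")
  if (any(abs(p$asymmetry_per_action) > 1))
    stop("asymmetry_per_action entries must lie in [-1, 1]")
  if (p$sample_rate <= 80)
    stop("sample_rate must exceed 2 x 40 Hz = 80 Hz")
  if (p$jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (p$alpha_freq < 6 || p$alpha_freq > 9)
    stop("alpha_freq must lie in [6, 9] Hz")
  if (p$drowsy_iteration_prob < 0 || p$drowsy_iteration_prob > 1)
    stop("drowsy_iteration_prob must lie in [0, 1]")
  if (p$noise_sd < 0 || p$artifact_rate < 0 || p$alpha_amp < 0)
    stop("noise_sd, artifact_rate and alpha_amp must be >= 0")
  if (p$burst_ms < 3000 || p$burst_ms > 8000)
    stop("burst_ms must lie in [3000, 8000]")
  if (p$n_channels < 14L || p$n_channels > 128L)
    stop("n_channels must lie in 14..128")
  class(p) <- "sim_params"
  p
}

# deterministic sub-seed, kept below 2^31
.subseed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1009L + k

#' Build the paradigm event schedule
#'
#' Two runs of eight actions: actions 1-4 performed in order, then repeated
#' (trial 2). Each action lasts 10 s, separated by 15-s pauses (consecutive
#' onsets 25 s apart within a run) with a 2-minute break between runs, a 2-s
#' lead-in before the first onset and a 2-s tail after the last epoch.
#' Iteration numbering is `2 (run - 1) + trial`, so each (action, iteration)
#' pair occurs exactly once per session.
#'
#' @param params a [sim_params()] object (only `sample_rate` is used).
#' @return an `event_schedule` with 16 events.
#' @export
build_schedule <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  rate <- params$sample_rate
  lead_s <- 2; action_s <- 10; pause_s <- 15; break_s <- 120
  rows <- list()
  t0 <- lead_s
  for (run in 1:2) {
    for (trial in 1:2) {
      for (action in 1:4) {
        idx <- (trial - 1L) * 4L + action   # position within the run (1..8)
        onset_s <- t0 + (idx - 1L) * (action_s + pause_s)
        rows[[length(rows) + 1L]] <- data.frame(
          onset_sample = as.integer(round(onset_s * rate)),
          action_id = action, iteration = 2L * (run - 1L) + trial,
          run = run, trial = trial)
      }
    }
    # next run starts after the last epoch ends plus the inter-run break
    t0 <- t0 + 7L * (action_s + pause_s) + action_s + break_s
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$onset_sample), ]
  rownames(ev) <- NULL
  new_schedule(ev, rate = rate, n_total = NA_integer_, action_s = action_s)
}

#' Generate a synthetic EEG session
#'
#' Produces a vertex-referenced recording spanning the full schedule. During
#' each action epoch the 14 frontal-cluster channels carry a Hann-windowed
#' alpha burst starting `response_delay_mean` plus a jitter draw after the
#' action onset; left-cluster amplitude is `alpha_amp (1 + a)` and right
#' `alpha_amp (1 - a)` where `a` is the action's entry in
#' `asymmetry_per_action`. Background 50/50 white + pink noise is added
#' everywhere, blink-like biphasic artifacts (150-300 uV, 200-400 ms) are
#' injected on frontal channels at `artifact_rate` per minute, and
#' `n_bad_channels` non-cluster channels are made flat or railed. Identical
#' parameters (including seed) give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @param montage an `eeg_montage`; defaults to the shipped 128-channel
#'   layout, subset to `params$n_channels`.
#' @return list with `recording` (an `eeg_recording`), `schedule`
#'   (an `event_schedule`) and `truth` (ground truth: `true_fas_per_action`,
#'   `true_lags_ms` 4 x 4 actions x iterations, `artifact_times`,
#'   `bad_channel_labels`).
#' @export
generate_session <- function(params, montage = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(montage)) montage <- read_montage()
  montage <- montage_subset(montage, params$n_channels)
  rate <- params$sample_rate
  sched <- build_schedule(params)
  action_len <- as.integer(round(10 * rate))
  n_total <- max(sched$onset_sample) + action_len +
    as.integer(round(2 * rate))

  set.seed(.subseed(params$seed, 1L))
  labs <- montage$labels
  nch <- length(labs)
  data <- matrix(0, nch, n_total)
  rownames(data) <- labs

  # background: equal-power white + pink noise per channel
  if (params$noise_sd > 0) {
    for (i in seq_len(nch)) {
      data[i, ] <- params$noise_sd *
        (rnorm(n_total) + .pink_noise(n_total)) / sqrt(2)
    }
  }

  # lateralized alpha bursts; jitter drawn per (action, iteration)
  true_lags <- matrix(NA_real_, 4, 4,
                      dimnames = list(action = 1:4, iteration = 1:4))
  li <- match(montage$left, labs)
  ri <- match(montage$right, labs)
  blen <- as.integer(round(params$burst_ms / 1000 * rate))
  win <- .hanning(blen)
  tt <- (seq_len(blen) - 1L) / rate
  for (r in seq_len(nrow(sched))) {
    a <- sched$action_id[r]; it <- sched$iteration[r]
    lag_ms <- params$response_delay_mean + rnorm(1L, 0, params$jitter_sd)
    true_lags[a, it] <- lag_ms
    start <- sched$onset_sample[r] + as.integer(round(lag_ms / 1000 * rate))
    idx <- start + seq_len(blen)          # 1-based column indices
    keep <- idx >= 1L & idx <= n_total
    if (!any(keep)) next
    phase <- runif(1L, 0, 2 * pi)
    wave <- (win * sin(2 * pi * params$alpha_freq * tt + phase))[keep]
    asym <- params$asymmetry_per_action[a]
    data[li, idx[keep]] <- data[li, idx[keep]] +
      rep(params$alpha_amp * (1 + asym) * wave, each = length(li))
    data[ri, idx[keep]] <- data[ri, idx[keep]] +
      rep(params$alpha_amp * (1 - asym) * wave, each = length(ri))
  }

  # blink-like biphasic artifacts on frontal channels
  artifact_times <- integer()
  if (params$artifact_rate > 0) {
    n_art <- rpois(1L, params$artifact_rate * n_total / rate / 60)
    if (n_art > 0) {
      onsets <- sort(sample.int(n_total - as.integer(0.5 * rate), n_art))
      fr <- c(li, ri)
      for (t0 in onsets) {
        dur <- runif(1L, 0.2, 0.4)                      # s
        amp <- runif(1L, 150, 300)                      # uV
        alen <- as.integer(round(dur * rate))
        pulse <- amp * sin(2 * pi * (seq_len(alen) - 1L) / alen)
        idx <- t0 + seq_len(alen)
        idx <- idx[idx <= n_total]
        data[fr, idx] <- data[fr, idx] +
          rep(pulse[seq_along(idx)], each = length(fr))
      }
      artifact_times <- onsets - 1L                     # 0-based
    }
  }

  # bad channels: alternate flat and railed, outside the clusters
  bad_labels <- character()
  if (params$n_bad_channels > 0L) {
    pool <- setdiff(labs, c(montage$left, montage$right))
    bad_labels <- sample(pool, min(params$n_bad_channels, length(pool)))
    for (k in seq_along(bad_labels)) {
      i <- match(bad_labels[k], labs)
      if (k %% 2L == 1L) {
        data[i, ] <- rnorm(n_total, 0, 0.01)            # flat
      } else {                                          # railed square wave
        data[i, ] <- 500 * sign(sin(2 * pi * 0.5 *
                                      (seq_len(n_total) - 1L) / rate))
      }
    }
  }

  truth <- list(
    true_fas_per_action = pmin(1, pmax(-1, params$asymmetry_per_action)),
    true_lags_ms = true_lags,
    artifact_times = artifact_times,
    bad_channel_labels = bad_labels)

  rec <- new_recording(data, rate = rate, labels = labs,
                       reference = "vertex")
  sched <- new_schedule(as.data.frame(sched), rate = rate,
                        n_total = n_total)
  list(recording = rec, schedule = sched, truth = truth)
}

# unit-variance 1/f noise via spectral shaping
.pink_noise <- function(n) {
  w <- rnorm(n)
  sp <- stats::fft(w)
  f <- seq_len(n) - 1L
  f <- pmin(f, n - f)
  scale <- 1 / sqrt(pmax(f, 1))
  x <- Re(stats::fft(sp * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate behavioural (WECS) codes for a session
#'
#' Scores in the three domains (facial expressiveness, sensitivity to
#' mother, vocal communication) are drawn from an ordered-categorical model:
#' a latent normal with mean `wecs_effect * (action - 1)` (flat when
#' `irritable`) cut at -0.75 and +0.75 into scores 1/2/3. Iterations are
#' flagged drowsy with probability `drowsy_iteration_prob`, in which case
#' sensitivity is coded 0. For irritable infants a small fraction of
#' iterations is inconsolable.
#'
#' @param params a [sim_params()] object.
#' @param truth ground truth from [generate_session()] (presence asserted;
#'   scores are conditionally independent of the EEG given the parameters).
#' @param infant_id identifier copied into the output table.
#' @return `data.frame` with columns `infant_id`, `action`, `iteration`,
#'   `domain`, `score`, `state` (one of `consolable_ok`, `drowsy`,
#'   `inconsolable`).
#' @export
generate_wecs <- function(params, truth, infant_id = "S01") {
  stopifnot(inherits(params, "sim_params"))
  if (missing(truth) || is.null(truth)) stop("ground truth required")
  set.seed(.subseed(params$seed, 2L))
  grid <- expand.grid(action = 1:4, iteration = 1:4)
  state <- rep("consolable_ok", nrow(grid))
  drowsy <- runif(nrow(grid)) < params$drowsy_iteration_prob
  state[drowsy] <- "drowsy"
  if (params$irritable) {
    incons <- runif(nrow(grid)) < 0.08 & !drowsy
    state[incons] <- "inconsolable"
  }
  doms <- c("facial", "sensitivity", "vocal")
  k <- nrow(grid)
  mu <- if (params$irritable) rep(0, k) else
    params$wecs_effect * (grid$action - 1L)
  z <- rnorm(3L * k, rep(mu, each = 3L), 1)   # domain-major within cell
  score <- 1L + (z > -0.75) + (z > 0.75)
  out <- data.frame(infant_id = infant_id,
                    action = rep(grid$action, each = 3L),
                    iteration = rep(grid$iteration, each = 3L),
                    domain = rep(doms, times = k),
                    score = score,
                    state = rep(state, each = 3L))
  out$score[out$state == "drowsy" & out$domain == "sensitivity"] <- 0L
  out
}

#' Generate dyad questionnaire metadata
#'
#' Consoling counts consistent with the irritability flag (irritable: two or
#' more consoling events and/or inconsolable iterations; non-irritable: at
#' most one), an MIBS bonding score (range 0-24, cohort median about 1) and
#' an EPDS depression screen (range 0-30, cohort median about 3).
#'
#' @param params a [sim_params()] object.
#' @param wecs WECS table from [generate_wecs()], used for the
#'   ever-inconsolable flag.
#' @param infant_id identifier.
#' @return one-row `data.frame`: `infant_id`, `consoling_events`,
#'   `ever_inconsolable`, `mibs`, `epds`.
#' @export
generate_meta <- function(params, wecs, infant_id = "S01") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(.subseed(params$seed, 3L))
  ever_inc <- any(wecs$state == "inconsolable")
  consoling <- if (params$irritable) sample(2:4, 1L)
  else sample(0:1, 1L)
  data.frame(infant_id = infant_id,
             consoling_events = consoling,
             ever_inconsolable = ever_inc,
             mibs = min(24L, rpois(1L, 1.3)),
             epds = min(30L, rpois(1L, 3)))
}

#' Simulate one complete dyad
#'
#' Bundles [generate_session()], [generate_wecs()] and [generate_meta()].
#'
#' @inheritParams generate_session
#' @param infant_id identifier.
#' @return list: `recording`, `schedule`, `truth`, `wecs`, `meta`.
#' @export
simulate_dyad <- function(params, montage = NULL, infant_id = "S01") {
  ses <- generate_session(params, montage)
  wecs <- generate_wecs(params, ses$truth, infant_id)
  meta <- generate_meta(params, wecs, infant_id)
  c(ses, list(wecs = wecs, meta = meta))
}

#' Simulate a cohort of dyads
#'
#' Infants are irritable with probability `p_irritable` (the study cohort was
#' about half irritable). Irritable infants receive a flat asymmetry
#' progression and a flat behavioural trend; non-irritable infants follow
#' `base_params`.
#'
#' @param n_infants number of dyads.
#' @param base_params [sim_params()] template for non-irritable infants.
#' @param p_irritable probability an infant is irritable.
#' @param seed cohort-level seed; per-infant seeds are derived from it.
#' @param irritable_asymmetry asymmetry profile for irritable infants.
#' @return list of dyads as returned by [simulate_dyad()].
#' @export
simulate_cohort <- function(n_infants, base_params = sim_params(),
                            p_irritable = 0.5, seed = 1L,
                            irritable_asymmetry = rep(-0.05, 4)) {
  set.seed(.subseed(seed, 4L))
  irr <- runif(n_infants) < p_irritable
  lapply(seq_len(n_infants), function(i) {
    p <- base_params
    p$seed <- .subseed(seed, 100L + i)
    p$irritable <- irr[i]
    if (irr[i]) {
      p$asymmetry_per_action <- irritable_asymmetry
      p$wecs_effect <- 0
    }
    simulate_dyad(p, infant_id = sprintf("S%02d", i))
  })
}
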