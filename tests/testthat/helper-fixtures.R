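# Shared fixtures. All simulated worlds are scaled down from the full
# 128-channel / 1000-Hz recording for CPU budget; noise_sd preserves the
# full-scale noise spectral density (10 uV broadband at 1000 Hz), i.e.
# noise_sd = 10 * sqrt(rate / 1000).

test_montage <- function(n = 30L) montage_subset(read_montage(), n)

# fast simulation world: 30 channels @ 200 Hz
test_params <- function(...) {
  args <- list(...)
  defaults <- list(n_channels = 30L, sample_rate = 200,
                   noise_sd = 10 * sqrt(200 / 1000), seed = 1L)
  defaults[names(args)] <- args
  do.call(sim_params, defaults)
}

# recovery-test world: 64 channels @ 250 Hz (average reference keeps
# frontal blink artifacts above the 120 uV rule at this channel count)
recovery_params <- function(...) {
  args <- list(...)
  defaults <- list(n_channels = 64L, sample_rate = 250,
                   noise_sd = 10 * sqrt(250 / 1000), seed = 1L)
  defaults[names(args)] <- args
  do.call(sim_params, defaults)
}

# bare recording from a matrix (labels default E1..En)
make_recording <- function(data, rate = 200,
                           labels = sprintf("E%d", seq_len(nrow(data))),
                           reference = "vertex", bad = character()) {
  new_recording(data, rate = rate, labels = labels, reference = reference,
                bad = bad)
}

# construct an action_epoch directly (unit tests of epoch-level operations)
make_epoch <- function(data, rate = 200, action_id = 1L, iteration = 1L,
                       labels = sprintf("E%d", seq_len(nrow(data)))) {
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels,
                 action_id = action_id, iteration = iteration,
                 run = 1L, trial = 1L, usable = TRUE,
                 masked = rep(FALSE, ncol(data)), masked_fraction = 0,
                 reason = NA_character_),
            class = "action_epoch")
}

# construct a cluster_envelope directly
make_envelope <- function(left, right, gfp = NULL, rate = 200,
                          mask = rep(FALSE, length(left))) {
  structure(list(left = left, right = right,
                 gfp = if (is.null(gfp)) (left + right) / 2 else gfp,
                 mask = mask, rate = rate, action_id = 1L, iteration = 1L,
                 usable = TRUE),
            class = "cluster_envelope")
}

# sinusoid recording helper
sine_recording <- function(freq, amp = 1, rate = 1000, dur_s = 10,
                           nch = 2L) {
  t <- (seq_len(rate * dur_s) - 1L) / rate
  data <- matrix(rep(amp * sin(2 * pi * freq * t), each = nch), nrow = nch)
  make_recording(data, rate = rate)
}

# interior RMS, discarding a fraction at each edge (filter edge effects)
interior <- function(x, frac = 0.1) {
  n <- length(x)
  k <- floor(n * frac)
  x[(k + 1L):(n - k)]
}
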