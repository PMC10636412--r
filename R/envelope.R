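# Alpha-band extraction, frontal-cluster signals, Hilbert envelopes and
# global field power per epoch.

#' Extract the infant alpha band from an epoch
#'
#' Butterworth band-pass, 6-9 Hz by default (the infant alpha band sits
#' below the adult 8-13 Hz convention), applied zero-phase. Order 2 gives
#' passband preservation at 7.5 Hz within 5% while attenuating 3 Hz and
#' 20 Hz by more than 90%.
#'
#' @param epoch an `action_epoch` (preprocessed).
#' @param low,high band edges in Hz.
#' @param order Butterworth order.
#' @return the epoch with band-limited `data`.
#' @export
alpha_filter <- function(epoch, low = 6, high = 9, order = 2L) {
  stopifnot(inherits(epoch, "action_epoch"))
  if (!(low > 0 && high > low && high < epoch$rate / 2))
    stop("invalid alpha band [", low, ", ", high, "]")
  epoch$data <- .fft_filter(epoch$data, epoch$rate,
                            function(f) butter_bandpass_gain(f, low, high,
                                                             order),
                            pad_s = 1)
  rownames(epoch$data) <- epoch$labels
  epoch
}

#' Average the seven-electrode clusters around F3 and F4
#'
#' Per-sample unweighted mean of the seven channels on each side.
#' Interpolated channels participate like any other channel; a cluster label
#' missing from the recording is a configuration error.
#'
#' @param epoch an `action_epoch`.
#' @param montage an `eeg_montage` defining exactly 7 labels per side.
#' @return list with numeric vectors `left` and `right`.
#' @export
cluster_average <- function(epoch, montage) {
  stopifnot(inherits(epoch, "action_epoch"), inherits(montage, "eeg_montage"))
  for (side in list(montage$left, montage$right)) {
    if (length(side) != 7L)
      stop("frontal cluster must have exactly 7 channels, got ",
           length(side))
    absent <- setdiff(side, epoch$labels)
    if (length(absent))
      stop("cluster channel(s) absent from recording: ",
           paste(absent, collapse = ", "))
  }
  list(left = colMeans(epoch$data[montage$left, , drop = FALSE]),
       right = colMeans(epoch$data[montage$right, , drop = FALSE]))
}

#' Alpha-band global field power of an epoch
#'
#' Per-sample standard deviation of voltage across all good channels, using
#' the population convention (divide by the channel count). For an
#' average-referenced epoch this is the RMS across channels, the
#' conventional reference-free measure of momentary field strength.
#'
#' @param epoch an `action_epoch` (alpha-filtered, average-referenced).
#' @param exclude channel labels to leave out (e.g. residual bad channels).
#' @return non-negative numeric vector, one value per sample.
#' @export
global_field_power <- function(epoch, exclude = character()) {
  stopifnot(inherits(epoch, "action_epoch"))
  keep <- setdiff(epoch$labels, exclude)
  if (length(keep) < 2L)
    stop("global field power requires at least 2 good channels")
  x <- epoch$data[keep, , drop = FALSE]
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

#' Cluster envelopes and GFP for one epoch
#'
#' Convenience wrapper producing the per-epoch quantities consumed by the
#' alignment stage: the Hilbert envelope of the left and right cluster
#' means (envelope of the cluster average, matching the processing order
#' average-then-envelope) and the alpha-band GFP, all sharing the epoch's
#' sample mask.
#'
#' @param epoch an alpha-filtered `action_epoch`.
#' @param montage an `eeg_montage`.
#' @return object of class `cluster_envelope`: list with `left`, `right`,
#'   `gfp`, `mask`, `rate`, `action_id`, `iteration`, `usable`.
#' @export
cluster_envelope <- function(epoch, montage) {
  cl <- cluster_average(epoch, montage)
  env <- list(left = hilbert_envelope(cl$left),
              right = hilbert_envelope(cl$right),
              gfp = global_field_power(epoch),
              mask = epoch$masked, rate = epoch$rate,
              action_id = epoch$action_id, iteration = epoch$iteration,
              usable = epoch$usable)
  class(env) <- "cluster_envelope"
  env
}
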