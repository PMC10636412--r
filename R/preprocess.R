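# Preprocessing chain: notch -> band-pass -> bad-channel detection ->
# interpolation -> average reference -> epoch segmentation -> amplitude
# artifact elimination. All filters are zero-phase (forward-backward
# equivalent); phase distortion ahead of Hilbert-envelope extraction would
# bias the cross-correlation alignment.

#' Power-line notch filter
#'
#' Butterworth band-stop centred on the mains frequency, applied zero-phase.
#' The magnitude response has an exact null at the centre frequency;
#' attenuation at 60 Hz far exceeds 20 dB while passband ripple at 10 Hz is
#' well under 1 dB.
#'
#' @param rec an `eeg_recording`.
#' @param freq mains frequency (Hz), default 60.
#' @param width stop-band width (Hz): the band is
#'   `[freq - width/2, freq + width/2]`.
#' @param order Butterworth order of the underlying prototype.
#' @return filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, freq = 60, width = 10, order = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$rate <= 2 * freq)
    stop("sampling rate ", rec$rate, " Hz too low to notch ", freq, " Hz")
  lo <- freq - width / 2
  hi <- freq * freq / lo   # geometric symmetry: exact null lands on `freq`
  out <- rec
  out$data <- .fft_filter(rec$data, rec$rate,
                          function(f) butter_bandstop_gain(f, lo, hi, order))
  rownames(out$data) <- rec$labels
  out
}

#' Butterworth band-pass filter
#'
#' Order-1 Butterworth, 0.3-40 Hz by default, applied zero-phase (so the
#' effective roll-off is that of the squared magnitude response). DC is
#' removed exactly (the response is 0 at 0 Hz).
#'
#' @param rec an `eeg_recording`.
#' @param low,high band edges in Hz; require `0 < low < high < rate/2`.
#' @param order nominal Butterworth order.
#' @return filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 0.3, high = 40, order = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && high > low && high < rec$rate / 2))
    stop("invalid band [", low, ", ", high, "] for rate ", rec$rate)
  out <- rec
  out$data <- .fft_filter(rec$data, rec$rate,
                          function(f) butter_bandpass_gain(f, low, high,
                                                           order),
                          pad_s = min(2, 0.6 / low))
  rownames(out$data) <- rec$labels
  out
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over all channels not marked bad.
#' Idempotent (a projection); the reference flag becomes `"average"`.
#'
#' @param rec an `eeg_recording` (vertex- or already average-referenced).
#' @return re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  good <- setdiff(rec$labels, rec$bad)
  if (length(good) == 0L) stop("all channels are bad; cannot re-reference")
  avg <- colMeans(rec$data[good, , drop = FALSE])
  out <- rec
  out$data <- sweep(rec$data, 2L, avg)
  out$reference <- "average"
  out
}

#' Detect unusable channels
#'
#' A channel is unusable when it is flat (SD below `flat_sd`) or extreme
#' (absolute amplitude above `amp_uv` for more than `extreme_frac` of
#' samples). This operationalises "unusable electrode data": the amplitude
#' criterion reuses the 120-uV artifact threshold as a channel-level screen.
#'
#' @param rec a filtered `eeg_recording`.
#' @param flat_sd flatness threshold (uV), default 0.1.
#' @param amp_uv amplitude threshold (uV), default 120.
#' @param extreme_frac tolerated fraction of extreme samples, default 0.2.
#' @return character vector of bad-channel labels.
#' @export
detect_bad_channels <- function(rec, flat_sd = 0.1, amp_uv = 120,
                                extreme_frac = 0.2) {
  stopifnot(inherits(rec, "eeg_recording"))
  sds <- apply(rec$data, 1L, stats::sd)
  frac_extreme <- rowMeans(abs(rec$data) > amp_uv)
  rec$labels[sds < flat_sd | frac_extreme > extreme_frac]
}

#' Interpolate bad channels from montage neighbours
#'
#' Each bad channel is replaced by the unweighted mean of its montage
#' neighbours that are themselves good; good channels are untouched. When
#' more than `max_bad` channels are bad the segment must be excluded rather
#' than repaired, which is signalled as a condition of class
#' `infasym_too_many_bad`.
#'
#' @param rec an `eeg_recording`.
#' @param bad labels to interpolate (defaults to `rec$bad`).
#' @param montage an `eeg_montage` supplying the adjacency.
#' @param max_bad exclusion ceiling (default 35 electrodes).
#' @return `eeg_recording` with repaired channels; `bad` is cleared for the
#'   repaired labels (they participate downstream as ordinary channels).
#' @export
interpolate_channels <- function(rec, bad = rec$bad, montage,
                                 max_bad = 35L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "eeg_montage"))
  bad <- unique(bad)
  if (length(bad) == 0L) return(rec)
  if (length(bad) > max_bad)
    stop(structure(class = c("infasym_too_many_bad", "error", "condition"),
                   list(message = sprintf(
                     "%d unusable channels exceed the ceiling of %d: segment must be excluded",
                     length(bad), max_bad), call = sys.call())))
  missing_lab <- setdiff(bad, rec$labels)
  if (length(missing_lab))
    stop("bad-channel labels not in recording: ",
         paste(missing_lab, collapse = ", "))
  out <- rec
  for (b in bad) {
    nb <- intersect(montage$neighbors[[b]], rec$labels)
    nb <- setdiff(nb, bad)
    if (length(nb) == 0L)
      stop("channel ", b, " has no good neighbours to interpolate from")
    out$data[b, ] <- colMeans(rec$data[nb, , drop = FALSE])
  }
  out$bad <- setdiff(rec$bad, bad)
  out
}

#' Segment a recording into 10-s action epochs
#'
#' One epoch per scheduled event, spanning `[onset, onset + 10 s)` after the
#' action onset trigger. Epochs that would extend past the end of the
#' recording are kept but marked unusable.
#'
#' @param rec a preprocessed `eeg_recording`.
#' @param sched an `event_schedule`.
#' @return list of `action_epoch` objects (fields: `data`, `rate`, `labels`,
#'   `action_id`, `iteration`, `run`, `trial`, `usable`, `masked` logical
#'   vector, `masked_fraction`, `reason`).
#' @export
segment_epochs <- function(rec, sched) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(sched, "event_schedule"))
  len <- as.integer(round(attr(sched, "action_s") * rec$rate))
  n <- n_samples(rec)
  lapply(seq_len(nrow(sched)), function(i) {
    on <- sched$onset_sample[i]
    usable <- on + len <= n
    cols <- if (usable) on + seq_len(len) else
      on + seq_len(max(0L, n - on))
    ep <- list(data = rec$data[, cols, drop = FALSE],
               rate = rec$rate, labels = rec$labels,
               action_id = sched$action_id[i],
               iteration = sched$iteration[i],
               run = sched$run[i], trial = sched$trial[i],
               usable = usable,
               masked = rep(FALSE, length(cols)),
               masked_fraction = 0,
               reason = if (usable) NA_character_ else "truncated epoch")
    class(ep) <- "action_epoch"
    ep
  })
}

#' Eliminate high-amplitude artifact samples from an epoch
#'
#' Samples at which any frontal-cluster channel exceeds the amplitude
#' threshold (120 uV) are masked, with a guard band extended `pad_ms` to
#' each side. The mask is carried through envelope extraction and window
#' averaging; an epoch more than `max_masked` masked becomes unusable.
#'
#' @param epoch an `action_epoch`.
#' @param montage an `eeg_montage`; the threshold is applied to the 14
#'   cluster channels (scope `"cluster"`) or to all channels (`"all"`).
#' @param threshold_uv amplitude threshold, default 120.
#' @param pad_ms guard band, default 100 ms per side.
#' @param max_masked usability ceiling on `masked_fraction`, default 0.5.
#' @param scope `"cluster"` or `"all"`.
#' @return the epoch with `masked`, `masked_fraction` and `usable` updated.
#' @export
eliminate_amplitude_artifacts <- function(epoch, montage,
                                          threshold_uv = 120,
                                          pad_ms = 100, max_masked = 0.5,
                                          scope = c("cluster", "all")) {
  stopifnot(inherits(epoch, "action_epoch"))
  scope <- match.arg(scope)
  chans <- if (scope == "cluster")
    intersect(c(montage$left, montage$right), epoch$labels)
  else epoch$labels
  if (length(chans) == 0L) stop("no channels in scope for artifact masking")
  hit <- apply(abs(epoch$data[chans, , drop = FALSE]) > threshold_uv,
               2L, any)
  pad <- as.integer(round(pad_ms / 1000 * epoch$rate))
  if (any(hit) && pad > 0L) {
    idx <- which(hit)
    lo <- pmax(1L, idx - pad)
    hi <- pmin(length(hit), idx + pad)
    for (k in seq_along(idx)) hit[lo[k]:hi[k]] <- TRUE
  }
  epoch$masked <- epoch$masked | hit
  epoch$masked_fraction <- mean(epoch$masked)
  if (epoch$masked_fraction > max_masked) {
    epoch$usable <- FALSE
    epoch$reason <- sprintf("masked_fraction %.2f > %.2f",
                            epoch$masked_fraction, max_masked)
  }
  epoch
}

#' @export
print.action_epoch <- function(x, ...) {
  cat(sprintf("<action_epoch> action %d iteration %d (run %d trial %d): %d ch x %d samples, masked %.1f%%%s\n",
              x$action_id, x$iteration, x$run, x$trial, nrow(x$data),
              ncol(x$data), 100 * x$masked_fraction,
              if (x$usable) "" else paste0(" [unusable: ", x$reason, "]")))
  invisible(x)
}
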