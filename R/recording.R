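# Canonical data model: EEG recordings and event schedules.

#' Construct an EEG recording
#'
#' The canonical in-memory container: a channels x samples matrix of
#' amplitudes in microvolts plus sampling rate, ordered channel labels, the
#' reference state, and the set of channels known to be bad.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param rate sampling rate in Hz (> 0).
#' @param labels character vector, one unique label per row of `data`.
#' @param reference `"vertex"` (as recorded) or `"average"`.
#' @param bad character vector of bad-channel labels (subset of `labels`).
#' @return object of class `eeg_recording`.
#' @export
new_recording <- function(data, rate, labels,
                          reference = c("vertex", "average"),
                          bad = character()) {
  reference <- match.arg(reference)
  if (!is.matrix(data)) stop("data must be a channels x samples matrix")
  if (length(labels) != nrow(data))
    stop("length(labels) [", length(labels), "] != rows(data) [",
         nrow(data), "]")
  if (anyDuplicated(labels))
    stop("duplicate channel label: ", labels[duplicated(labels)][1])
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  if (anyNA(data)) stop("recording contains NA/NaN amplitudes")
  if (!all(bad %in% labels))
    stop("bad channels not in labels: ",
         paste(setdiff(bad, labels), collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels,
                 reference = reference, bad = unique(bad)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              x$reference))
  if (length(x$bad)) cat(", bad:", paste(x$bad, collapse = " "))
  cat("\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Construct and validate an event schedule
#'
#' Events mark action onsets in the interaction paradigm: four distinct
#' maternal actions, each performed twice per run (two trials) in two runs,
#' giving four iterations per action and 16 events per session. Onsets are
#' 0-based sample indices; epochs are half-open `[onset, onset + 10 s)`.
#'
#' @param events data.frame with columns `onset_sample`, `action_id` (1-4),
#'   `iteration` (1-4), `run` (1-2), `trial` (1-2).
#' @param rate sampling rate (Hz) used to check epoch extents.
#' @param n_total total recording length in samples, or `NA` to skip the
#'   in-bounds check.
#' @param action_s epoch duration in seconds (default 10).
#' @return a validated `event_schedule` (data.frame subclass).
#' @export
new_schedule <- function(events, rate, n_total = NA_integer_, action_s = 10) {
  need <- c("onset_sample", "action_id", "iteration", "run", "trial")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("schedule missing columns: ",
                         paste(miss, collapse = ", "))
  events <- as.data.frame(events)[need]
  bad_action <- which(!(events$action_id %in% 1:4))
  if (length(bad_action))
    stop("invalid action_id at row ", bad_action[1], ": ",
         events$action_id[bad_action[1]])
  if (!all(events$iteration %in% 1:4)) stop("iteration must be in 1..4")
  if (!all(events$run %in% 1:2)) stop("run must be in 1..2")
  if (!all(events$trial %in% 1:2)) stop("trial must be in 1..2")
  if (is.unsorted(events$onset_sample, strictly = TRUE))
    stop("onsets must be strictly increasing")
  if (any(events$onset_sample < 0)) stop("onsets must be >= 0")
  key <- paste(events$action_id, events$run, events$trial)
  if (anyDuplicated(key))
    stop("duplicate (action_id, run, trial): ", key[duplicated(key)][1])
  if (!is.na(n_total)) {
    len <- as.integer(round(action_s * rate))
    over <- which(events$onset_sample + len > n_total)
    if (length(over))
      stop("epoch extends beyond recording at row ", over[1],
           " (onset ", events$onset_sample[over[1]], " + ", len,
           " > ", n_total, ")")
  }
  structure(events, class = c("event_schedule", "data.frame"),
            rate = rate, action_s = action_s)
}
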