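# Frontal asymmetry scores.

#' Frontal asymmetry score
#'
#' `FAS = (F3 - F4) / (F3 + F4)` on the mean alpha envelope amplitude of the
#' left (F3) and right (F4) frontal clusters. Bounded in `[-1, 1]`;
#' 0 indicates similar alpha amplitude over the two hemispheres, positive
#' values left-lateralized alpha. The score is scale-invariant
#' (`FAS(cL, cR) = FAS(L, R)` for `c > 0`) and antisymmetric in its
#' arguments. Note the sign is reported exactly as defined here; the
#' conventional inverse-activity reading of alpha power (more alpha = less
#' cortical activity) is a matter of interpretation, not applied to the
#' numbers.
#'
#' @param mean_left,mean_right non-negative mean envelope amplitudes (uV);
#'   vectorised.
#' @param power `"amplitude"` uses the envelope means as given;
#'   `"squared"` squares them first (alpha power rather than amplitude).
#' @return FAS in `[-1, 1]`; `NA` when both inputs are 0 (logged upstream).
#' @export
compute_fas <- function(mean_left, mean_right,
                        power = c("amplitude", "squared")) {
  power <- match.arg(power)
  if (any(mean_left < 0 | mean_right < 0, na.rm = TRUE))
    stop("envelope means must be non-negative")
  l <- if (power == "squared") mean_left^2 else mean_left
  r <- if (power == "squared") mean_right^2 else mean_right
  out <- ifelse(l + r == 0, NA_real_, (l - r) / (l + r))
  out
}

#' Log-ratio asymmetry (documented utility)
#'
#' `ln(L) - ln(R)`, the other index in common use; provided for comparison
#' only, the pipeline reports the bounded ratio form.
#'
#' @inheritParams compute_fas
#' @return log-ratio asymmetry; `NA` when either side is 0.
#' @export
fas_log_ratio <- function(mean_left, mean_right) {
  ifelse(mean_left <= 0 | mean_right <= 0, NA_real_,
         log(mean_left) - log(mean_right))
}

#' Subtract the action-1 baseline from FAS values
#'
#' Action 1 (mother present but not engaging) serves as within-infant
#' baseline; its FAS is subtracted from actions 2-4, yielding three values
#' per infant. Missing actions propagate as missing; a missing baseline
#' invalidates all three deltas.
#'
#' @param raw_fas numeric length-4 vector of per-action FAS (action 1
#'   first), possibly with `NA`.
#' @return named numeric length-3 vector (`action2`..`action4`), each in
#'   `[-2, 2]` or `NA`; attribute `baseline_missing` is `TRUE` when action 1
#'   was absent.
#' @export
baseline_subtract <- function(raw_fas) {
  if (length(raw_fas) != 4L) stop("raw_fas must have length 4")
  base_missing <- is.na(raw_fas[1L])
  delta <- if (base_missing) rep(NA_real_, 3L) else raw_fas[2:4] - raw_fas[1L]
  names(delta) <- paste0("action", 2:4)
  attr(delta, "baseline_missing") <- base_missing
  delta
}
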