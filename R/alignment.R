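# Within-infant alignment of the four iterations of each action by
# cross-correlation of alpha-band global field power, followed by response
# window extraction and averaging.
#
# Lag convention: `lag > 0` means the iteration's response occurs LATER than
# the reference iteration's, so its extraction window is shifted later by
# the same amount. For ground-truth onset delays d_i the recovered lag of
# iteration i approximates d_i - d_ref.

#' Normalized cross-correlation lag search (direct form)
#'
#' Brute-force reference implementation: for every integer lag in
#' `[-max_lag, max_lag]` computes the normalized cross-correlation over the
#' jointly valid overlapping region of the two series and returns the full
#' correlation curve. Each series is centred on the mean of its valid
#' samples; invalid (masked) samples contribute neither to the numerator
#' nor to the normalization. Used as the oracle for the FFT path and for
#' small inputs.
#'
#' @param ref,x numeric vectors of common length.
#' @param max_lag maximum |lag| in samples.
#' @param ref_valid,x_valid logical vectors: which samples are usable
#'   (default: all).
#' @return numeric vector of correlations, one per lag `-max_lag..max_lag`.
#' @export
xcorr_lags_direct <- function(ref, x, max_lag,
                              ref_valid = NULL, x_valid = NULL) {
  n <- length(ref)
  stopifnot(length(x) == n, max_lag < n)
  if (is.null(ref_valid)) ref_valid <- rep(TRUE, n)
  if (is.null(x_valid)) x_valid <- rep(TRUE, n)
  r0 <- (ref - mean(ref[ref_valid])) * ref_valid
  x0 <- (x - mean(x[x_valid])) * x_valid
  vapply(-max_lag:max_lag, function(tau)
    .ncc_at(r0, x0, ref_valid, x_valid, tau), numeric(1))
}

# exact masked NCC at a single integer lag (shared by both engines)
.ncc_at <- function(r0, x0, wr, wx, tau) {
  n <- length(r0)
  if (tau >= 0) {
    ir <- seq_len(n - tau); ix <- tau + ir
  } else {
    ix <- seq_len(n + tau); ir <- (-tau) + ix
  }
  num <- sum(r0[ir] * x0[ix])
  den <- sqrt(sum(r0[ir]^2 * wx[ix]) * sum(wr[ir] * x0[ix]^2))
  if (den == 0) 0 else num / den
}

# centred moving average with edge shrinkage (window truncated at edges)
.moving_average <- function(x, w) {
  half <- w %/% 2L
  cs <- c(0, cumsum(x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# widen a logical mask by k samples on each side of every TRUE run
.dilate_mask <- function(mask, k) {
  if (k <= 0L || !any(mask)) return(mask)
  idx <- which(mask)
  out <- logical(length(mask))
  lo <- pmax(1L, idx - k)
  hi <- pmin(length(mask), idx + k)
  for (j in seq_along(idx)) out[lo[j]:hi[j]] <- TRUE
  out
}

# FFT version of xcorr_lags_direct: three cross-correlations (signal x
# signal, signal^2 x validity, validity x signal^2) give numerator and
# masked normalization terms; identical definition up to floating point.
.xcorr_lags_fft <- function(ref, x, max_lag, ref_valid = NULL,
                            x_valid = NULL) {
  n <- length(ref)
  if (is.null(ref_valid)) ref_valid <- rep(TRUE, n)
  if (is.null(x_valid)) x_valid <- rep(TRUE, n)
  wr <- as.numeric(ref_valid)
  wx <- as.numeric(x_valid)
  r0 <- (ref - mean(ref[ref_valid])) * wr
  x0 <- (x - mean(x[x_valid])) * wx
  m <- stats::nextn(2L * n, c(2L, 3L, 5L))
  pad <- function(v) c(v, numeric(m - n))
  F <- function(v) stats::fft(pad(v))
  xc <- function(a_f, b_f)   # xc[tau] = sum_t b[t] a[t + tau]
    Re(stats::fft(a_f * Conj(b_f), inverse = TRUE)) / m
  lags <- -max_lag:max_lag
  pick <- ifelse(lags >= 0, lags + 1L, m + lags + 1L)
  f_x0 <- F(x0); f_r0 <- F(r0)
  f_x02 <- F(x0^2); f_r02 <- F(r0^2)
  f_wx <- F(wx); f_wr <- F(wr)
  num <- xc(f_x0, f_r0)[pick]
  den_r <- xc(f_wx, f_r02)[pick]    # sum_t r0^2[t] wx[t + tau]
  den_x <- xc(f_x02, f_wr)[pick]    # sum_t wr[t] x0^2[t + tau]
  den2 <- den_r * den_x
  ifelse(den2 <= 0, 0, num / sqrt(pmax(den2, 0)))
}

#' Align iterations of an action by GFP cross-correlation
#'
#' The first usable iteration serves as reference (lag 0). Each other
#' iteration's lag maximises the normalized cross-correlation with the
#' reference over integer lags within `max_lag_ms`; ties are broken toward
#' the smallest absolute lag. Masked samples (dilated, see below) are
#' excluded from both the correlation numerator and its normalization.
#'
#' @param gfps list of GFP series (equal length, common rate); `NULL`
#'   entries denote unusable iterations.
#' @param rate sampling rate (Hz).
#' @param max_lag_ms lag search bound (ms), default 2000.
#' @param masks optional list of logical masks matching `gfps`.
#' @param engine `"fft"` (default) or `"direct"` (brute force oracle).
#' @param mask_dilate_ms widening of the artifact mask, per side, before
#'   exclusion (default 300 ms). Amplitude artifacts are masked with
#'   a 100-ms guard for window averaging, but band-pass ringing extends
#'   further and sub-threshold artifact tails carry alpha-band energy; a
#'   wider guard keeps them from dominating the correlation peak.
#' @param smooth_ms moving-average width applied to each GFP series before
#'   correlation (default 133 ms, one period of mid-band infant alpha).
#'   The GFP of a narrow-band oscillation ripples at twice the oscillation
#'   frequency; without smoothing the correlation peak locks onto cycle
#'   alignment (half-period quantization of lags) rather than onto the
#'   response profile. Set to 0 to correlate the raw GFP.
#' @return numeric vector of lags in ms (NA for unusable iterations);
#'   attribute `reference` gives the reference iteration index.
#' @export
align_iterations <- function(gfps, rate, max_lag_ms = 2000, masks = NULL,
                             engine = c("fft", "direct"),
                             mask_dilate_ms = 300, smooth_ms = 133) {
  engine <- match.arg(engine)
  usable <- which(!vapply(gfps, is.null, logical(1)))
  if (length(usable) < 2L)
    stop(structure(class = c("infasym_too_few_iterations", "error",
                             "condition"),
                   list(message = "fewer than 2 usable iterations: action dropped",
                        call = sys.call())))
  dil <- as.integer(round(mask_dilate_ms / 1000 * rate))
  sm <- as.integer(round(smooth_ms / 1000 * rate))
  clean <- function(i) {
    g <- gfps[[i]]
    valid <- rep(TRUE, length(g))
    if (!is.null(masks) && !is.null(masks[[i]]) && any(masks[[i]])) {
      mk <- .dilate_mask(masks[[i]], dil)
      if (all(mk)) mk <- masks[[i]]
      valid <- !mk
    }
    if (sm > 1L) {           # mask-aware moving average
      num <- .moving_average(g * valid, sm)
      den <- .moving_average(as.numeric(valid), sm)
      g <- ifelse(den > 0, num / den, 0)
      valid <- den > 0.5     # windows mostly masked stay invalid
    }
    list(g = g, valid = valid)
  }
  ref_i <- usable[1L]
  ref <- clean(ref_i)
  max_lag <- min(as.integer(round(max_lag_ms / 1000 * rate)),
                 length(ref$g) - 1L)
  lags_ms <- rep(NA_real_, length(gfps))
  lags_ms[ref_i] <- 0
  lag_axis <- -max_lag:max_lag
  for (i in setdiff(usable, ref_i)) {
    x <- clean(i)
    if (engine == "fft") {
      # FFT curve locates the peak; candidate lags within float tolerance
      # of the maximum are re-evaluated with exact direct sums so the
      # selected lag always equals the brute-force search
      cc <- .xcorr_lags_fft(ref$g, x$g, max_lag, ref$valid, x$valid)
      cand <- which(cc >= max(cc) - 1e-6)
      r0 <- (ref$g - mean(ref$g[ref$valid])) * ref$valid
      x0 <- (x$g - mean(x$g[x$valid])) * x$valid
      exact <- vapply(lag_axis[cand], function(tau)
        .ncc_at(r0, x0, ref$valid, x$valid, tau), numeric(1))
      best <- cand[exact == max(exact)]
    } else {
      cc <- xcorr_lags_direct(ref$g, x$g, max_lag, ref$valid, x$valid)
      best <- which(cc == max(cc))
    }
    if (length(best) > 1L) best <- best[which.min(abs(lag_axis[best]))]
    lags_ms[i] <- lag_axis[best] / rate * 1000
  }
  attr(lags_ms, "reference") <- ref_i
  lags_ms
}

#' Mean cluster envelope over the aligned response window
#'
#' Averages the unmasked envelope samples in the window
#' `[delay + lag, delay + lag + length)` relative to epoch onset: a 2000-ms
#' response delay followed by a 5000-ms analysis window, shifted by the
#' iteration's recovered lag. Windows that leave the epoch are clamped to
#' it (logged via the `clamped` field). The first and last `edge_trim`
#' fraction of epoch samples are excluded from means to suppress Hilbert
#' edge effects.
#'
#' @param env a `cluster_envelope`.
#' @param lag_ms recovered lag for this iteration (ms).
#' @param delay_ms response delay, default 2000.
#' @param length_ms window length, default 5000.
#' @param max_masked exclusion ceiling on the masked fraction of the
#'   window, default 0.5.
#' @param edge_trim fraction of epoch samples trimmed per edge (default
#'   0.05).
#' @return list `mean_left`, `mean_right`, `n_samples`, `clamped`,
#'   `excluded`, `reason`.
#' @export
extract_window <- function(env, lag_ms, delay_ms = 2000, length_ms = 5000,
                           max_masked = 0.5, edge_trim = 0.05) {
  stopifnot(inherits(env, "cluster_envelope"))
  n <- length(env$left)
  rate <- env$rate
  start <- as.integer(round((delay_ms + lag_ms) / 1000 * rate))  # 0-based
  len <- as.integer(round(length_ms / 1000 * rate))
  lo <- start
  hi <- start + len                       # half-open [lo, hi)
  clamped <- FALSE
  if (lo < 0L) { lo <- 0L; clamped <- TRUE }
  if (hi > n) { hi <- n; clamped <- TRUE }
  if (hi <= lo)
    return(list(mean_left = NA_real_, mean_right = NA_real_,
                n_samples = 0L, clamped = TRUE, excluded = TRUE,
                reason = "window entirely outside epoch"))
  idx <- (lo + 1L):hi                     # 1-based
  trim <- as.integer(floor(edge_trim * n))
  keep <- idx > trim & idx <= n - trim & !env$mask[idx]
  frac_masked <- mean(env$mask[idx])
  if (frac_masked > max_masked || !any(keep))
    return(list(mean_left = NA_real_, mean_right = NA_real_,
                n_samples = 0L, clamped = clamped, excluded = TRUE,
                reason = sprintf("window masked fraction %.2f > %.2f",
                                 frac_masked, max_masked)))
  list(mean_left = mean(env$left[idx[keep]]),
       mean_right = mean(env$right[idx[keep]]),
       n_samples = sum(keep), clamped = clamped, excluded = FALSE,
       reason = NA_character_)
}

#' Average iteration windows into one action summary
#'
#' Unweighted mean of the per-iteration window means; at least two usable
#' iterations are required (an action with fewer is dropped, matching the
#' retention rule that actions keep >= 2 trials).
#'
#' @param windows list of [extract_window()] results.
#' @param action_id action identifier carried into the output.
#' @param lags_ms per-iteration lags carried into the output.
#' @return list of class `aligned_action`: `action_id`, `mean_left`,
#'   `mean_right`, `n_iterations_used`, `lags_ms`; or `NULL` when dropped.
#' @export
average_action <- function(windows, action_id = NA_integer_,
                           lags_ms = NULL) {
  ok <- Filter(function(w) !isTRUE(w$excluded) && is.finite(w$mean_left),
               windows)
  if (length(ok) < 2L) return(NULL)
  out <- list(action_id = action_id,
              mean_left = mean(vapply(ok, `[[`, 0, "mean_left")),
              mean_right = mean(vapply(ok, `[[`, 0, "mean_right")),
              n_iterations_used = length(ok),
              lags_ms = lags_ms)
  class(out) <- "aligned_action"
  out
}
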