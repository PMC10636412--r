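# Readers and writers for the canonical data model.
#
# EDF: a minimal self-contained 16-bit EDF codec (no R EDF package is
# available in the supported environment). One data record per second;
# recordings whose length is not a whole number of seconds are zero-padded
# on disk and the true sample count is stored in the header's reserved field
# so the round trip is length-exact. Physical dimensions restricted to
# uV/mV; anything else is rejected rather than silently mis-scaled.
#
# HDF5 (via rhdf5): lossless container; datasets /data (channels x samples,
# uV), /labels, /bad, attributes sample_rate and reference on /data.

#' Write an EEG recording to disk
#'
#' @param rec an `eeg_recording`.
#' @param path output file.
#' @param format `"edf"` (16-bit, quantized to ~0.01 uV for typical scalp
#'   ranges) or `"hdf5"` (lossless).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "hdf5")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  switch(format,
         edf = .write_edf(rec, path),
         hdf5 = .write_h5(rec, path))
  invisible(path)
}

#' Read an EEG recording
#'
#' Amplitudes are returned in microvolts regardless of the on-disk unit
#' (EDF signals declared in mV are scaled by 1000; other physical dimensions
#' are rejected). The reference state defaults to `"vertex"` when the file
#' carries no reference metadata.
#'
#' @param path input file.
#' @param format `"edf"` or `"hdf5"`.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("edf", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         edf = .read_edf(path),
         hdf5 = .read_h5(path))
}

.pad_str <- function(s, n) {
  s <- substr(s, 1L, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

# format a number into <= 8 ascii chars, dropping precision as needed
.num8 <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d, width = 1)
      if (nchar(s) <= 8L) return(.pad_str(s, 8L))
    }
    .pad_str("0", 8L)
  }, "")
}

.write_edf <- function(rec, path) {
  rate <- rec$rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  rate <- as.integer(round(rate))
  nch <- nrow(rec$data)
  n <- ncol(rec$data)
  nrec <- as.integer(ceiling(n / rate))
  npad <- nrec * rate - n

  pmin_ <- apply(rec$data, 1L, min)
  pmax_ <- apply(rec$data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-6
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  # header values are re-parsed from their 8-char ascii form so that the
  # scaling used for encoding matches decoding exactly
  pmin_ <- as.numeric(.num8(pmin_)); pmax_ <- as.numeric(.num8(pmax_))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad_str("0", 8L),
    .pad_str("X X X X", 80L),
    .pad_str("Startdate X X X X", 80L),
    "01.01.00", "00.00.00",
    .pad_str(as.character(256L * (nch + 1L)), 8L),
    .pad_str(sprintf("NS=%d", n), 44L),       # true sample count (dialect)
    .pad_str(as.character(nrec), 8L),
    .pad_str("1", 8L),                         # record duration 1 s
    .pad_str(as.character(nch), 4L))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w)
    writeChar(paste0(vapply(vals, .pad_str, "", n = w), collapse = ""),
              con, eos = NULL)
  field(rec$labels, 16L)
  field(rep("", nch), 80L)
  field(rep("uV", nch), 8L)
  field(.num8(pmin_), 8L)
  field(.num8(pmax_), 8L)
  field(rep("-32768", nch), 8L)
  field(rep("32767", nch), 8L)
  field(rep(if (length(rec$bad))
    paste0("BAD:", paste(rec$bad, collapse = ";")) else "", nch), 80L)
  field(rep(as.character(rate), nch), 8L)
  field(rep(rec$reference, nch), 32L)

  scale <- (pmax_ - pmin_) / 65535
  dig <- matrix(0L, nch, nrec * rate)
  for (i in seq_len(nch)) {
    x <- c(rec$data[i, ], rep(pmin_[i], npad))
    d <- as.integer(round((x - pmin_[i]) / scale[i]) - 32768L)
    dig[i, ] <- pmin(32767L, pmax(-32768L, d))
  }
  for (r in seq_len(nrec)) {
    cols <- (r - 1L) * rate + seq_len(rate)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  hdr_bytes <- as.integer(rd(8L))
  reserved <- rd(44L)
  nrec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  nch <- as.integer(rd(4L))
  if (is.na(nch) || nch < 1L) stop("EDF: bad channel count field")
  fld <- function(w) {
    s <- rd(w * nch)
    trimws(substring(s, (seq_len(nch) - 1L) * w + 1L, seq_len(nch) * w))
  }
  labels <- fld(16L); fld(80L)
  dim_ <- fld(8L)
  pmin_ <- as.numeric(fld(8L)); pmax_ <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  prefilter <- fld(80L)
  spr <- as.integer(fld(8L))
  sig_res <- fld(32L)
  if (anyDuplicated(labels))
    stop("EDF: duplicate channel label: ", labels[duplicated(labels)][1])
  unit_scale <- ifelse(dim_ %in% c("uV", "µV"), 1,
                       ifelse(dim_ == "mV", 1000, NA_real_))
  if (anyNA(unit_scale))
    stop("EDF: unsupported physical dimension '",
         dim_[is.na(unit_scale)][1], "' (need uV or mV)")
  if (length(unique(spr)) != 1L)
    stop("EDF: heterogeneous sampling rates are not supported")
  rate <- spr[1L] / dur

  data <- matrix(0, nch, nrec * spr[1L])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    blk <- readBin(con, "integer", n = nch * spr[1L], size = 2L,
                   signed = TRUE, endian = "little")
    if (length(blk) < nch * spr[1L]) stop("EDF: truncated data record ", r)
    blk <- matrix(blk, nrow = spr[1L], ncol = nch)
    cols <- (r - 1L) * spr[1L] + seq_len(spr[1L])
    data[, cols] <- t(blk) * scale + (pmin_ - dmin * scale)
  }
  data <- data * unit_scale
  ns <- sub("^NS=([0-9]+).*$", "\\1", reserved)
  if (grepl("^[0-9]+$", ns)) {
    ns <- as.integer(ns)
    if (ns <= ncol(data)) data <- data[, seq_len(ns), drop = FALSE]
  }
  bad <- character()
  pf <- prefilter[1L]
  if (grepl("^BAD:", pf))
    bad <- strsplit(sub("^BAD:", "", pf), ";", fixed = TRUE)[[1L]]
  reference <- if (sig_res[1L] %in% c("vertex", "average"))
    sig_res[1L] else "vertex"
  if (anyNA(data)) stop("EDF: NA amplitudes after decoding")
  new_recording(data, rate = rate, labels = labels,
                reference = reference, bad = bad)
}

.write_h5 <- function(rec, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$data, path, "data")
  rhdf5::h5write(rec$labels, path, "labels")
  rhdf5::h5write(rec$bad, path, "bad")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "data")
  rhdf5::h5writeAttribute(rec$rate, did, "sample_rate")
  rhdf5::h5writeAttribute(rec$reference, did, "reference")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

.read_h5 <- function(path) {
  data <- rhdf5::h5read(path, "data")
  labels <- as.character(rhdf5::h5read(path, "labels"))
  bad <- as.character(rhdf5::h5read(path, "bad"))
  at <- rhdf5::h5readAttributes(path, "data")
  if (is.null(at$sample_rate)) stop("HDF5: missing sample_rate attribute")
  ref <- if (!is.null(at$reference)) as.character(at$reference) else "vertex"
  new_recording(data, rate = as.numeric(at$sample_rate), labels = labels,
                reference = ref, bad = bad)
}

#' Write an event schedule as CSV
#' @param sched an `event_schedule`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_events <- function(sched, path) {
  utils::write.csv(as.data.frame(sched), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate an event schedule CSV
#'
#' Required columns: `onset_sample` (0-based), `action_id` (1-4),
#' `iteration` (1-4), `run` (1-2), `trial` (1-2). Onsets must be strictly
#' increasing; when `n_total` is given, epochs must fit inside the
#' recording.
#'
#' @param path CSV file.
#' @param rate sampling rate (Hz) of the recording the events index into.
#' @param n_total recording length in samples (optional bounds check).
#' @return an `event_schedule`.
#' @export
read_events <- function(path, rate, n_total = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  new_schedule(df, rate = rate, n_total = n_total)
}

#' Read a WECS behavioural coding table
#'
#' Columns: `infant_id`, `action` (1-4), `iteration` (1-4), `domain`
#' (facial/sensitivity/vocal), `score` (0-3), `state`
#' (consolable_ok/drowsy/inconsolable). A sensitivity score of 0 is only
#' legal on drowsy iterations; scores outside 0..3 are rejected.
#'
#' @param path CSV file.
#' @return validated `data.frame`.
#' @export
read_wecs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_wecs(df)
}

#' Validate a WECS table (see [read_wecs()] for the contract)
#' @param df data.frame.
#' @return the validated data.frame, invisibly classed.
#' @export
validate_wecs <- function(df) {
  need <- c("infant_id", "action", "iteration", "domain", "score", "state")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("WECS table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$score %in% 0:3))
    stop("WECS scores must be in {0,1,2,3}; found ",
         df$score[!df$score %in% 0:3][1])
  if (!all(df$domain %in% c("facial", "sensitivity", "vocal")))
    stop("unknown WECS domain")
  if (!all(df$state %in% c("consolable_ok", "drowsy", "inconsolable")))
    stop("unknown behavioural state")
  zero_bad <- df$score == 0 &
    !(df$domain == "sensitivity" & df$state == "drowsy")
  if (any(zero_bad))
    stop("score 0 is only legal for sensitivity on drowsy iterations (row ",
         which(zero_bad)[1], ")")
  df
}

#' Read dyad metadata
#'
#' Columns: `infant_id`, `consoling_events` (count), `ever_inconsolable`
#' (logical), `mibs` (0-24), `epds` (0-30).
#'
#' @param path CSV file.
#' @return validated `data.frame`.
#' @export
read_dyad_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("infant_id", "consoling_events", "ever_inconsolable",
            "mibs", "epds")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$mibs < 0 | df$mibs > 24))
    stop("MIBS out of range 0-24 for infant ",
         df$infant_id[df$mibs < 0 | df$mibs > 24][1])
  if (any(df$epds < 0 | df$epds > 30))
    stop("EPDS out of range 0-30 for infant ",
         df$infant_id[df$epds < 0 | df$epds > 30][1])
  if (any(df$consoling_events < 0)) stop("negative consoling_events")
  df
}
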