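#' Construct a continuous EEG recording
#'
#' The canonical container for multichannel continuous data. Samples are
#' stored channel-by-time in microvolts; time is in seconds; sample indices
#' are 0-based and windows are half-open `[start, end)` throughout the
#' package.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate_hz sampling rate in samples per second. The study devices run
#'   at 500 Hz (scalp) and 600 Hz (in-ear) but any positive rate is accepted.
#' @param channel_labels character vector naming the rows of `samples`,
#'   e.g. `c("Fz","Cz","Pz","EOG")` for scalp or `c("L","R")` for in-ear data.
#' @param start_offset_s recording start time in seconds (default 0).
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(samples, rate_hz, channel_labels, start_offset_s = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop_totonou("`samples` must be a numeric channels x time matrix", "bad_samples")
  }
  if (anyNA(samples)) stop_totonou("ragged channels: missing samples", "ragged_channels")
  check_scalar_number(rate_hz, "rate_hz", lower = .Machine$double.eps)
  check_scalar_number(start_offset_s, "start_offset_s")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples) || anyDuplicated(channel_labels)) {
    stop_totonou("`channel_labels` must uniquely name every channel", "bad_channels")
  }
  rownames(samples) <- channel_labels
  structure(
    list(
      samples = samples, rate_hz = as.numeric(rate_hz),
      channel_labels = channel_labels, start_offset_s = as.numeric(start_offset_s)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) [%s], %d samples @ %g Hz (%.3f s)\n",
    nrow(x$samples), paste(x$channel_labels, collapse = ","),
    ncol(x$samples), x$rate_hz, recording_duration(x)
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$rate_hz

#' Assert that a recording carries the channels a stage expects
#'
#' Downstream stages are channel-specific: scalp stages need Fz/Cz/Pz (+EOG),
#' in-ear stages need L/R. Order is not constrained.
#'
#' @param rec an `eeg_recording`.
#' @param expected character vector of required channel labels.
#' @return `rec`, invisibly.
#' @export
require_channels <- function(rec, expected) {
  missing <- setdiff(expected, rec$channel_labels)
  if (length(missing) > 0L) {
    stop_totonou(
      sprintf("recording lacks required channel(s): %s", paste(missing, collapse = ", ")),
      "channel_mismatch"
    )
  }
  invisible(rec)
}

#' Construct an event-marker table
#'
#' One row per stimulus. `sample_index` is 0-based into the recording;
#' `kind` is `"standard"` or `"target"`; response fields are only meaningful
#' for targets.
#'
#' @param sample_index non-negative integer vector of onset samples.
#' @param kind character vector, `"standard"` or `"target"`.
#' @param response_time_ms reaction times in ms (`NA` for standards and
#'   missed targets).
#' @param responded_correctly logical (`NA` for standards).
#' @param n_samples optional recording length used to validate indices.
#' @return a `data.frame` of class `event_markers`.
#' @export
new_event_markers <- function(sample_index, kind,
                              response_time_ms = NA_real_,
                              responded_correctly = NA,
                              n_samples = NULL) {
  n <- length(sample_index)
  ev <- data.frame(
    sample_index = as.integer(sample_index),
    kind = as.character(kind),
    response_time_ms = as.numeric(rep_len(response_time_ms, n)),
    responded_correctly = as.logical(rep_len(responded_correctly, n))
  )
  if (any(ev$sample_index < 0L)) stop_totonou("negative sample_index", "bad_markers")
  if (!all(ev$kind %in% c("standard", "target"))) {
    stop_totonou("marker kind must be 'standard' or 'target'", "bad_markers")
  }
  std <- ev$kind == "standard"
  if (any(std & (!is.na(ev$response_time_ms) | !is.na(ev$responded_correctly)))) {
    stop_totonou("response fields present on standard markers", "bad_markers")
  }
  if (any(!is.na(ev$response_time_ms) & ev$response_time_ms <= 0)) {
    stop_totonou("response_time_ms must be positive", "bad_markers")
  }
  if (!is.null(n_samples) && any(ev$sample_index >= n_samples)) {
    stop_totonou("marker sample_index beyond recording end", "bad_markers")
  }
  class(ev) <- c("event_markers", "data.frame")
  ev
}

# ---- delimited recording IO -------------------------------------------------
# Data file: one column per channel, one row per sample, tab-separated, header
# row of channel labels. Metadata (rate, unit, offset) in a YAML sidecar
# "<path>.meta" so fixtures need no binary dependency.

sidecar_path <- function(path) paste0(path, ".meta")

#' Write a recording to disk
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param dialect `"delimited"` (tab-separated text plus a `<path>.meta` YAML
#'   sidecar; lossless) or `"edf"` (16-bit European Data Format; quantised to
#'   the recording's amplitude range and padded to whole data records).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("delimited", "edf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "eeg_recording"))
  if (dialect == "edf") return(write_edf(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  body <- apply(rec$samples, 2L, function(col) paste(sprintf("%.17g", col), collapse = "\t"))
  writeLines(body, con)
  meta <- list(
    format = "totonou-recording", unit = "microvolt",
    rate_hz = rec$rate_hz, start_offset_s = rec$start_offset_s,
    channels = as.list(rec$channel_labels)
  )
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path file path (for the delimited dialect a `<path>.meta` YAML
#'   sidecar declaring the sampling rate must sit beside it).
#' @param dialect `"delimited"` or `"edf"`.
#' @return an `eeg_recording` in microvolts.
#' @export
read_recording <- function(path, dialect = c("delimited", "edf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_totonou(sprintf("unreadable file: %s", path), "unreadable_file")
  }
  if (dialect == "edf") return(read_edf(path))
  meta_file <- sidecar_path(path)
  if (!file.exists(meta_file)) {
    stop_totonou("missing rate: no metadata sidecar found", "missing_rate")
  }
  meta <- yaml::read_yaml(meta_file)
  if (is.null(meta$rate_hz)) stop_totonou("missing rate in sidecar", "missing_rate")
  lines <- readLines(path)
  if (length(lines) < 1L) stop_totonou("empty recording file", "unreadable_file")
  labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(fields) > 0L && any(nf != length(labels))) {
    stop_totonou("ragged channels: rows differ in column count", "ragged_channels")
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) stop_totonou("non-numeric sample values", "unreadable_file")
  samples <- matrix(vals, nrow = length(labels))
  scale <- switch(tolower(meta$unit %||% "microvolt"),
    microvolt = 1, millivolt = 1e3, volt = 1e6,
    stop_totonou(sprintf("unknown unit '%s'", meta$unit), "bad_unit")
  )
  new_recording(samples * scale, meta$rate_hz, labels,
    start_offset_s = meta$start_offset_s %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF support ----------------------------------------------------
# 16-bit EDF with one-second data records; enough for round-tripping the
# study's continuous recordings. No annotations, one transducer-free header
# per signal.

edf_pad <- function(x, width) {
  formatC(substr(as.character(x), 1L, width), width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  spr <- as.integer(round(rec$rate_hz))
  if (abs(spr - rec$rate_hz) > 1e-9) {
    stop_totonou("EDF dialect needs an integer sampling rate", "bad_parameter")
  }
  n_rec <- as.integer(ceiling(ncol(rec$samples) / spr))
  pad <- n_rec * spr - ncol(rec$samples)
  x <- cbind(rec$samples, matrix(0, ns, pad))
  # integer physical bounds: they must print inside 8-character header fields
  pmin_ <- floor(apply(x, 1L, min))
  pmax_ <- ceiling(apply(x, 1L, max))
  flat <- pmax_ - pmin_ < 1
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  if (any(abs(c(pmin_, pmax_)) >= 1e7)) {
    stop_totonou("amplitudes too large for the EDF header fields", "bad_parameter")
  }
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad("X X X X", 80L), edf_pad("Startdate X X X X", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (ns + 1L), 8L), edf_pad("", 44L),
    edf_pad(n_rec, 8L), edf_pad(1L, 8L), edf_pad(ns, 4L)
  )
  sig <- paste0(
    paste(edf_pad(rec$channel_labels, 16L), collapse = ""),
    paste(rep(edf_pad("", 80L), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8L), ns), collapse = ""),
    paste(edf_pad(sprintf("%d", as.integer(pmin_)), 8L), collapse = ""),
    paste(edf_pad(sprintf("%d", as.integer(pmax_)), 8L), collapse = ""),
    paste(rep(edf_pad(dmin, 8L), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8L), ns), collapse = ""),
    paste(rep(edf_pad("", 80L), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8L), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((x[ch, idx] - pmin_[ch]) / gain[ch]) + dmin)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L) # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop_totonou("not an EDF file", "unreadable_file")
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16L); fld(80L); fld(8L)
  pmin_ <- as.numeric(fld(8L)); pmax_ <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L))
  if (length(unique(spr)) != 1L) {
    stop_totonou("ragged channels: per-signal rates differ", "ragged_channels")
  }
  if (is.na(rec_dur) || rec_dur <= 0) stop_totonou("missing rate", "missing_rate")
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  out <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     signed = TRUE, endian = "little")
      out[ch, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  new_recording(out, spr[1L] / rec_dur, labels)
}

# ---- event and table IO -----------------------------------------------------

#' Write event markers beside a recording
#' @param events an `event_markers` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read event markers
#' @param path path written by [write_events()].
#' @return an `event_markers` table.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_totonou(sprintf("unreadable file: %s", path), "unreadable_file")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_event_markers(d$sample_index, d$kind, d$response_time_ms, d$responded_correctly)
}

#' Write a derived-measure table as delimited text
#'
#' Rows are sorted by every column left to right so output is deterministic
#' regardless of the order measures were computed in.
#'
#' @param rows a `data.frame` of derived measures.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) > 1L) {
    rows <- rows[do.call(order, unname(as.list(rows))), , drop = FALSE]
  }
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path input path.
#' @return a `data.frame`.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop_totonou(sprintf("unreadable file: %s", path), "unreadable_file")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
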