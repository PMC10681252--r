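# Filtering, epoching, fixed-length segmentation and amplitude-threshold
# artifact rejection for the two recording paths (scalp oddball: 0.1-30 Hz,
# -100..600 ms epochs, +-50 uV; in-ear rest: 2-30 Hz, 8 s segments, +-100 uV).

butterworth_gain2 <- function(f, low_hz, high_hz, order) {
  # squared magnitude of an order-`order` Butterworth band-pass, i.e. the
  # response a forward-backward (zero-phase) application realizes
  g <- rep(1, length(f))
  if (low_hz > 0) {
    r <- ifelse(f == 0, Inf, low_hz / f)
    g <- g / (1 + r^(2 * order))
  }
  if (is.finite(high_hz)) g <- g / (1 + (f / high_hz)^(2 * order))
  g
}

fft_zero_phase <- function(x, rate_hz, low_hz, high_hz, order) {
  n <- length(x)
  xx <- c(x, rev(x)) # mirror pad: removes circular wrap-around transients
  m <- length(xx)
  k <- 0:(m - 1L)
  f <- ifelse(k <= m %/% 2, k, k - m) * rate_hz / m
  g <- butterworth_gain2(abs(f), low_hz, high_hz, order)
  Re(stats::fft(stats::fft(xx) * g, inverse = TRUE) / m)[seq_len(n)]
}

#' Zero-phase band-pass filter
#'
#' Applies the squared magnitude response of a Butterworth band-pass --
#' exactly what forward-backward (zero-phase) filtering realizes -- in the
#' frequency domain with mirror padding. Component latencies are unshifted;
#' the realization is numerically stable even at the 0.1 Hz cutoff used for
#' the scalp path, where a time-domain transfer-function recursion is
#' ill-conditioned.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz high-pass cutoff in Hz (0 disables; scalp path uses 0.1,
#'   in-ear path 2).
#' @param high_hz low-pass cutoff in Hz (both paths use 30; the decoder path
#'   uses 45). Must be below the Nyquist frequency.
#' @param order Butterworth order per pass (default 4).
#' @return the filtered `eeg_recording`.
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_scalar_number(low_hz, "low_hz", lower = 0)
  check_scalar_number(high_hz, "high_hz", lower = 0)
  if (low_hz >= high_hz || high_hz >= rec$rate_hz / 2) {
    stop_totonou("cutoffs must satisfy 0 <= low < high < rate/2", "nyquist")
  }
  out <- rec
  out$samples <- t(apply(rec$samples, 1L, fft_zero_phase,
    rate_hz = rec$rate_hz, low_hz = low_hz, high_hz = high_hz, order = order
  ))
  rownames(out$samples) <- rec$channel_labels
  out
}

new_epoch_set <- function(data, times_s, channels, condition, rate_hz,
                          n_edge_dropped = 0L) {
  structure(
    list(
      data = data, times_s = times_s, channels = channels,
      condition = condition, rate_hz = rate_hz,
      kept = rep(TRUE, dim(data)[1L]),
      rejection_reason = rep(NA_character_, dim(data)[1L]),
      n_edge_dropped = as.integer(n_edge_dropped)
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> condition=%s: %d epochs (%d kept, %d edge-dropped), %d ch x %d samples\n",
    x$condition, dim(x$data)[1L], sum(x$kept), x$n_edge_dropped,
    dim(x$data)[2L], dim(x$data)[3L]
  ))
  invisible(x)
}

#' Cut stimulus-locked epochs from a recording
#'
#' Epochs run from `tmin_s` before to `tmax_s` after each marker (half-open
#' window), are baseline-corrected by subtracting the per-channel mean of the
#' `[-100, 0)` ms pre-stimulus interval, and are grouped by stimulus kind.
#' Markers whose window would cross a recording edge are dropped with reason
#' `"edge"` and counted in `n_edge_dropped`.
#'
#' @param rec an `eeg_recording` (scalp path: already filtered 0.1-30 Hz).
#' @param markers an `event_markers` table.
#' @param tmin_s epoch start relative to stimulus onset (default -0.1 s).
#' @param tmax_s epoch end relative to onset (default 0.6 s).
#' @param baseline_s two-element window used for baseline correction
#'   (default `c(-0.1, 0)`).
#' @return a named list with one `epoch_set` per condition present
#'   (`standard`, `target`).
#' @export
epoch_recording <- function(rec, markers, tmin_s = -0.1, tmax_s = 0.6,
                            baseline_s = c(-0.1, 0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$rate_hz
  len <- as.integer(round((tmax_s - tmin_s) * rate))
  if (len < 2L) stop_totonou("epoch window too short", "bad_parameter")
  offset <- as.integer(round(tmin_s * rate))
  times <- tmin_s + (0:(len - 1L)) / rate
  bl <- times >= baseline_s[1L] & times < baseline_s[2L]
  n <- ncol(rec$samples)
  out <- list()
  for (cond in intersect(c("standard", "target"), unique(markers$kind))) {
    onsets <- markers$sample_index[markers$kind == cond]
    start <- onsets + offset # 0-based
    ok <- start >= 0L & (start + len) <= n
    dat <- array(0, dim = c(sum(ok), nrow(rec$samples), len))
    for (i in seq_along(which(ok))) {
      s <- start[which(ok)[i]]
      ep <- rec$samples[, (s + 1L):(s + len), drop = FALSE]
      if (any(bl)) ep <- ep - rowMeans(ep[, bl, drop = FALSE])
      dat[i, , ] <- ep
    }
    out[[cond]] <- new_epoch_set(dat, times, rec$channel_labels, cond, rate,
      n_edge_dropped = sum(!ok)
    )
  }
  out
}

#' Flag epochs exceeding an amplitude threshold
#'
#' Marks `kept = FALSE` (reason `"amplitude"`) for every epoch in which any
#' monitored channel exceeds `threshold_uv` in absolute value -- the
#' automatic rejection rule for vertical eye movement and muscle artifacts.
#' Sample data are never mutated; only the keep flags change.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts (default 50, the
#'   scalp/EOG epoch rule).
#' @param channels channels to monitor (default: all, EOG included).
#' @return the `epoch_set` with updated `kept`/`rejection_reason`.
#' @export
reject_epochs <- function(epochs, threshold_uv = 50, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  check_scalar_number(threshold_uv, "threshold_uv", lower = 0)
  if (is.null(channels)) channels <- epochs$channels
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop_totonou("unknown monitor channel", "channel_mismatch")
  bad <- apply(abs(epochs$data[, ci, , drop = FALSE]), 1L, max) > threshold_uv
  newly <- bad & epochs$kept
  epochs$kept[newly] <- FALSE
  epochs$rejection_reason[newly] <- "amplitude"
  epochs
}

new_segment_set <- function(data, segment_length_s, channels, rate_hz) {
  structure(
    list(
      data = data, segment_length_s = segment_length_s,
      channels = channels, rate_hz = rate_hz,
      kept = rep(TRUE, dim(data)[1L]),
      rejection_reason = rep(NA_character_, dim(data)[1L])
    ),
    class = "segment_set"
  )
}

#' Cut a recording into consecutive fixed-length segments
#'
#' Segments are non-overlapping and consecutive; a trailing remainder shorter
#' than `length_s` is discarded. The in-ear spectral path uses 8 s segments,
#' the decoder path 4 s.
#'
#' @param rec an `eeg_recording`.
#' @param length_s segment length in seconds.
#' @return a `segment_set` (segments x channels x time array plus keep flags).
#' @export
segment_recording <- function(rec, length_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_scalar_number(length_s, "length_s", lower = .Machine$double.eps)
  len <- as.integer(round(length_s * rec$rate_hz))
  n_seg <- ncol(rec$samples) %/% len
  if (n_seg < 1L) {
    stop_totonou("recording shorter than one segment", "too_short")
  }
  dat <- array(0, dim = c(n_seg, nrow(rec$samples), len))
  for (i in seq_len(n_seg)) {
    dat[i, , ] <- rec$samples[, ((i - 1L) * len + 1L):(i * len)]
  }
  new_segment_set(dat, length_s, rec$channel_labels, rec$rate_hz)
}

#' Flag segments exceeding an amplitude threshold
#'
#' The in-ear counterpart of [reject_epochs()]: segments in which the signal
#' exceeds `threshold_uv` (default 100) in absolute value on any monitored
#' channel are flagged as rejected.
#'
#' @param segments a `segment_set`.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @param channels channels to monitor (default: all).
#' @return the `segment_set` with updated flags.
#' @export
reject_segments <- function(segments, threshold_uv = 100, channels = NULL) {
  stopifnot(inherits(segments, "segment_set"))
  check_scalar_number(threshold_uv, "threshold_uv", lower = 0)
  if (is.null(channels)) channels <- segments$channels
  ci <- match(channels, segments$channels)
  if (anyNA(ci)) stop_totonou("unknown monitor channel", "channel_mismatch")
  bad <- apply(abs(segments$data[, ci, , drop = FALSE]), 1L, max) > threshold_uv
  newly <- bad & segments$kept
  segments$kept[newly] <- FALSE
  segments$rejection_reason[newly] <- "amplitude"
  segments
}

#' Rejection log for an epoch or segment set
#' @param x an `epoch_set` or `segment_set`.
#' @return a `data.frame` with one row per window: index, kept, reason.
#' @export
rejection_log <- function(x) {
  data.frame(
    index = seq_along(x$kept), kept = x$kept,
    reason = x$rejection_reason, stringsAsFactors = FALSE
  )
}
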