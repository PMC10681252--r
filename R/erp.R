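# Condition averaging, difference waveform, MMN / P300 quantification and
# reaction-time summaries for the auditory oddball task.

#' Average kept epochs into a per-channel ERP waveform
#'
#' @param epochs an `epoch_set`.
#' @return numeric matrix, channels x time (microvolts), the pointwise mean
#'   across kept epochs only.
#' @export
average_erp <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- which(epochs$kept)
  if (length(keep) == 0L) stop_totonou("no usable epochs", "no_usable_epochs")
  avg <- apply(epochs$data[keep, , , drop = FALSE], c(2L, 3L), mean)
  rownames(avg) <- epochs$channels
  avg
}

#' Polarity-clipped area of an ERP component
#'
#' Integrates (trapezoidal rule) the polarity-matching portion of a waveform
#' over a half-open latency window: for `"negative"` the integrand is
#' `min(x, 0)` (MMN convention, area <= 0), for `"positive"` it is
#' `max(x, 0)` (P300 convention, area >= 0). Units are microvolt-milliseconds.
#'
#' @param waveform numeric vector (microvolts), typically one channel of the
#'   target-minus-standard difference waveform.
#' @param times_ms latencies of `waveform` relative to stimulus onset, in ms.
#' @param window_ms two-element half-open window `[lo, hi)` in ms. The study
#'   scores MMN over `[100, 250)` and P300 over `[240, 400)`.
#' @param polarity `"negative"` or `"positive"`.
#' @return signed area in microvolt-milliseconds.
#' @export
component_area <- function(waveform, times_ms, window_ms,
                           polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(length(waveform) == length(times_ms), length(window_ms) == 2L)
  if (window_ms[1L] < min(times_ms) || window_ms[2L] > max(times_ms) + diff(times_ms[1:2])) {
    stop_totonou("scoring window outside epoch span", "window_outside_span")
  }
  inside <- times_ms >= window_ms[1L] & times_ms < window_ms[2L]
  x <- waveform[inside]
  t <- times_ms[inside]
  if (length(x) < 2L) stop_totonou("scoring window too narrow", "window_outside_span")
  x <- if (polarity == "negative") pmin(x, 0) else pmax(x, 0)
  sum(diff(t) * (x[-length(x)] + x[-1L]) / 2)
}

component_peak <- function(waveform, times_ms, window_ms, polarity) {
  inside <- times_ms >= window_ms[1L] & times_ms < window_ms[2L]
  x <- waveform[inside]
  t <- times_ms[inside]
  i <- if (polarity == "negative") which.min(x) else which.max(x)
  c(amplitude_uv = x[i], latency_ms = t[i])
}

#' ERP measures from one oddball session
#'
#' Averages kept standard and target epochs, forms the target-minus-standard
#' difference waveform per channel, and scores MMN (negative, 100-250 ms) and
#' P300 (positive, 240-400 ms) on it. The primary measure is the
#' polarity-clipped area; the extremum amplitude and its latency within each
#' window are reported alongside (the `measure` switch selects which fills
#' the `mmn`/`p300` columns).
#'
#' @param epochs_by_condition named list with `standard` and `target`
#'   `epoch_set`s, as returned by [epoch_recording()].
#' @param mmn_window_ms MMN scoring window (default `c(100, 250)`).
#' @param p300_window_ms P300 scoring window (default `c(240, 400)`).
#' @param measure `"area"` (microvolt-ms, default) or `"peak"` (extremum
#'   amplitude in microvolts).
#' @return an `erp_result`: list with `standard_avg`, `target_avg`,
#'   `difference` (channels x time matrices), `times_ms`, `n_epochs_used`,
#'   and a per-channel `scores` data.frame.
#' @export
erp_measures <- function(epochs_by_condition,
                         mmn_window_ms = c(100, 250),
                         p300_window_ms = c(240, 400),
                         measure = c("area", "peak")) {
  measure <- match.arg(measure)
  for (cond in c("standard", "target")) {
    if (is.null(epochs_by_condition[[cond]])) {
      stop_totonou(sprintf("missing '%s' epochs", cond), "no_usable_epochs")
    }
  }
  std <- average_erp(epochs_by_condition$standard)
  tgt <- average_erp(epochs_by_condition$target)
  stopifnot(identical(dim(std), dim(tgt)))
  diff_wave <- tgt - std
  times_ms <- epochs_by_condition$target$times_s * 1000
  channels <- epochs_by_condition$target$channels
  scores <- do.call(rbind, lapply(channels, function(ch) {
    w <- diff_wave[ch, ]
    mmn_pk <- component_peak(w, times_ms, mmn_window_ms, "negative")
    p3_pk <- component_peak(w, times_ms, p300_window_ms, "positive")
    data.frame(
      channel = ch,
      mmn_area = component_area(w, times_ms, mmn_window_ms, "negative"),
      p300_area = component_area(w, times_ms, p300_window_ms, "positive"),
      mmn_peak_uv = unname(mmn_pk["amplitude_uv"]),
      mmn_peak_latency_ms = unname(mmn_pk["latency_ms"]),
      p300_peak_uv = unname(p3_pk["amplitude_uv"]),
      p300_peak_latency_ms = unname(p3_pk["latency_ms"]),
      stringsAsFactors = FALSE
    )
  }))
  scores$mmn <- if (measure == "area") scores$mmn_area else scores$mmn_peak_uv
  scores$p300 <- if (measure == "area") scores$p300_area else scores$p300_peak_uv
  structure(
    list(
      standard_avg = std, target_avg = tgt, difference = diff_wave,
      times_ms = times_ms,
      n_epochs_used = c(
        standard = sum(epochs_by_condition$standard$kept),
        target = sum(epochs_by_condition$target$kept)
      ),
      scores = scores, measure = measure
    ),
    class = "erp_result"
  )
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf(
    "<erp_result> %d standard / %d target epochs averaged; measure = %s\n",
    x$n_epochs_used["standard"], x$n_epochs_used["target"], x$measure
  ))
  print(x$scores[, c("channel", "mmn_area", "p300_area")], row.names = FALSE)
  invisible(x)
}

#' Reaction-time summary over correct target responses
#'
#' @param markers an `event_markers` table for one session.
#' @return a one-row `data.frame` with `mean_rt_ms`, `sd_rt_ms` and
#'   `n_correct`; only correct target responses enter the summary.
#' @export
rt_summary <- function(markers) {
  ok <- markers$kind == "target" &
    !is.na(markers$responded_correctly) & markers$responded_correctly &
    !is.na(markers$response_time_ms)
  if (!any(ok)) stop_totonou("no correct target responses", "no_correct_responses")
  rt <- markers$response_time_ms[ok]
  data.frame(
    mean_rt_ms = mean(rt),
    sd_rt_ms = if (length(rt) > 1L) stats::sd(rt) else NA_real_,
    n_correct = length(rt)
  )
}
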