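# Per-segment Fourier power, individual alpha frequency (IAF) estimation and
# the five IAF-anchored band powers for two-channel in-ear recordings.

#' Names of the five analysis bands
#' @return character vector of band names in canonical order.
#' @export
band_names <- function() c("theta", "lower1_alpha", "lower2_alpha", "upper_alpha", "beta")

#' IAF-anchored band edges
#'
#' The four alpha-adjacent bands tile `[IAF-6, IAF+2)` with half-open,
#' lower-inclusive intervals; beta is fixed at `[15, 30)`.
#'
#' @param iaf_hz individual alpha frequency in Hz.
#' @return a 5 x 2 matrix of `[lo, hi)` edges, rows named by band.
#' @export
band_edges <- function(iaf_hz) {
  check_scalar_number(iaf_hz, "iaf_hz", lower = 6)
  m <- rbind(
    theta = c(iaf_hz - 6, iaf_hz - 4),
    lower1_alpha = c(iaf_hz - 4, iaf_hz - 2),
    lower2_alpha = c(iaf_hz - 2, iaf_hz),
    upper_alpha = c(iaf_hz, iaf_hz + 2),
    beta = c(15, 30)
  )
  colnames(m) <- c("lo", "hi")
  m
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)

# One-sided periodogram of a single window. Power is normalized so the sum
# over all bins equals the mean square of the (taper-corrected) signal in
# microvolts squared: sum(P) ~= mean(x^2) for broadband signals, and a unit
# sinusoid carries total power 1/2.
periodogram <- function(x, rate_hz, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n <- length(x)
  w <- if (taper == "hann") hann_window(n) else rep(1, n)
  xf <- stats::fft(x * w)
  nk <- n %/% 2L
  p <- Mod(xf[1:(nk + 1L)])^2 / (n^2 * mean(w^2))
  # one-sided doubling (DC and, for even n, Nyquist appear once)
  dbl <- rep(2, nk + 1L)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[nk + 1L] <- 1
  list(freqs_hz = (0:nk) * rate_hz / n, power = p * dbl)
}

#' Per-segment power spectra of kept segments
#'
#' Computes a tapered periodogram for every kept segment and channel. With
#' the default Hann taper, power is renormalized by the taper's mean square
#' so that broadband power and sinusoid power are preserved (the internal
#' Parseval identity `sum(power) == mean((w*x)^2)/mean(w^2)` holds exactly;
#' see the methods vignette).
#'
#' @param segments a `segment_set` (8 s segments for the band-power path).
#' @param taper `"hann"` (default; suppresses leakage into the narrow
#'   IAF-anchored bands) or `"none"`.
#' @return a `power_spectrum`: list with `freqs_hz`, `power` (array
#'   segment x channel x frequency, microvolts squared), `resolution_hz`
#'   (`1 / segment_length_s`), and `channels`.
#' @export
power_spectrum <- function(segments, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  stopifnot(inherits(segments, "segment_set"))
  keep <- which(segments$kept)
  if (length(keep) == 0L) stop_totonou("no kept segments", "no_kept_segments")
  n_ch <- length(segments$channels)
  first <- periodogram(segments$data[keep[1L], 1L, ], segments$rate_hz, taper)
  pw <- array(0, dim = c(length(keep), n_ch, length(first$freqs_hz)))
  for (i in seq_along(keep)) {
    for (ch in seq_len(n_ch)) {
      pw[i, ch, ] <- periodogram(segments$data[keep[i], ch, ], segments$rate_hz, taper)$power
    }
  }
  structure(
    list(
      freqs_hz = first$freqs_hz, power = pw,
      resolution_hz = 1 / segments$segment_length_s,
      channels = segments$channels, taper = taper
    ),
    class = "power_spectrum"
  )
}

#' Estimate the individual alpha frequency
#'
#' The IAF is the frequency of peak power within 8-13 Hz (inclusive) of the
#' segment- and channel-averaged spectrum of the pre-sauna rest data. Ties
#' are broken toward the lower frequency; the estimate lies on the spectrum's
#' frequency grid (0.125 Hz for 8 s segments).
#'
#' @param spectrum a `power_spectrum` from the pre-sauna phase.
#' @param search_lo,search_hi search interval in Hz (default 8 and 13).
#' @return the IAF in Hz.
#' @export
estimate_iaf <- function(spectrum, search_lo = 8, search_hi = 13) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  mean_pw <- apply(spectrum$power, 3L, mean)
  inside <- spectrum$freqs_hz >= search_lo & spectrum$freqs_hz <= search_hi
  if (!any(inside)) stop_totonou("no frequency bins inside the alpha search range", "no_alpha_bins")
  f <- spectrum$freqs_hz[inside]
  p <- mean_pw[inside]
  f[which.max(p)] # which.max returns the first (lowest-frequency) maximum
}

#' Gross absolute band power in the five IAF-anchored bands
#'
#' Sums bin powers over each half-open band interval and averages across
#' kept segments, separately per channel (L and R are never pooled).
#'
#' @param spectrum a `power_spectrum`.
#' @param iaf_hz the participant's IAF from [estimate_iaf()] (pre-sauna data).
#' @return a `data.frame` with columns `channel`, `band`, `power_uv2`,
#'   `iaf_hz`.
#' @export
band_powers <- function(spectrum, iaf_hz) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (iaf_hz - 6 < 0) stop_totonou("iaf_hz - 6 must be >= 0", "bad_parameter")
  edges <- band_edges(iaf_hz)
  f <- spectrum$freqs_hz
  rows <- list()
  for (b in rownames(edges)) {
    inside <- f >= edges[b, "lo"] & f < edges[b, "hi"]
    if (!any(inside)) {
      stop_totonou(sprintf("band '%s' contains no frequency bins", b), "empty_band")
    }
    # mean over segments of the summed bin power, per channel
    per_seg <- apply(spectrum$power[, , inside, drop = FALSE], c(1L, 2L), sum)
    rows[[b]] <- data.frame(
      channel = spectrum$channels, band = b,
      power_uv2 = colMeans(per_seg), iaf_hz = iaf_hz,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$band <- factor(out$band, levels = band_names())
  out
}
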