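# Synthetic study generator: oddball sessions with injected MMN/P300
# deflections, two-channel in-ear rest recordings with an individual alpha
# peak and controlled band powers, blink/muscle artifacts that trip the
# rejection thresholds, and whole cohorts with condition-dependent effects
# so every analysis stage is testable without raw data.

#' ERP shape parameters for the oddball simulator
#'
#' Components are Gaussian-shaped deflections added to every target epoch;
#' the background is an equal-power mix of pink (1/f) and white noise.
#' Defaults place the components at the centre of their scoring windows.
#'
#' @param mmn_amplitude_uv MMN peak amplitude in microvolts (<= 0).
#' @param mmn_latency_ms MMN peak latency in ms (inside `[100, 250)`).
#' @param p300_amplitude_uv P300 peak amplitude in microvolts (>= 0).
#' @param p300_latency_ms P300 peak latency in ms (inside `[240, 400)`).
#' @param component_width_ms Gaussian sd of both components in ms; must be
#'   narrow enough that >= 90% of each component's mass lies inside its
#'   scoring window.
#' @param background_noise_sd_uv sd of the background noise in microvolts
#'   (0 gives a noiseless session).
#' @param blink_rate_per_min expected blink count per minute on the EOG
#'   channel.
#' @param blink_amplitude_uv blink peak amplitude in microvolts (a 300 ms
#'   half-sine on EOG, bleeding 20% into the scalp channels).
#' @return a list of class `erp_shape_params`.
#' @export
erp_shape_params <- function(mmn_amplitude_uv = -5, mmn_latency_ms = 175,
                             p300_amplitude_uv = 6, p300_latency_ms = 320,
                             component_width_ms = 20,
                             background_noise_sd_uv = 8,
                             blink_rate_per_min = 2,
                             blink_amplitude_uv = 120) {
  check_scalar_number(mmn_amplitude_uv, "mmn_amplitude_uv", upper = 0)
  check_scalar_number(mmn_latency_ms, "mmn_latency_ms", 100, 250)
  check_scalar_number(p300_amplitude_uv, "p300_amplitude_uv", lower = 0)
  check_scalar_number(p300_latency_ms, "p300_latency_ms", 240, 400)
  check_scalar_number(component_width_ms, "component_width_ms", lower = .Machine$double.eps)
  check_scalar_number(background_noise_sd_uv, "background_noise_sd_uv", lower = 0)
  check_scalar_number(blink_rate_per_min, "blink_rate_per_min", lower = 0)
  check_scalar_number(blink_amplitude_uv, "blink_amplitude_uv", lower = 0)
  mass <- function(lat, w, win) {
    stats::pnorm((win[2] - lat) / w) - stats::pnorm((win[1] - lat) / w)
  }
  if (mass(mmn_latency_ms, component_width_ms, c(100, 250)) < 0.9 ||
    mass(p300_latency_ms, component_width_ms, c(240, 400)) < 0.9) {
    stop_totonou("component mass must lie >= 90% inside its scoring window", "bad_parameter")
  }
  structure(
    list(
      mmn_amplitude_uv = mmn_amplitude_uv, mmn_latency_ms = mmn_latency_ms,
      p300_amplitude_uv = p300_amplitude_uv, p300_latency_ms = p300_latency_ms,
      component_width_ms = component_width_ms,
      background_noise_sd_uv = background_noise_sd_uv,
      blink_rate_per_min = blink_rate_per_min,
      blink_amplitude_uv = blink_amplitude_uv
    ),
    class = "erp_shape_params"
  )
}

#' Spectral parameters for the in-ear rest simulator
#'
#' The rest signal is synthesised in the frequency domain: a pink (1/f)
#' baseline plus the five analysis bands, each scaled so its realised power
#' equals `band_power_targets`. The two alpha bands adjacent to the IAF take
#' Gaussian-flank spectral shapes peaking at `iaf_hz`, so the spectrum shows
#' an individual alpha peak; the remaining bands are flat. Phases are random,
#' making the oscillations narrow-band noise rather than pure sinusoids.
#'
#' @param iaf_hz individual alpha peak frequency in Hz (8-13).
#' @param band_power_targets named numeric vector of target band powers in
#'   microvolts squared; names must be exactly the five analysis bands.
#' @param pink_noise_exponent exponent of the 1/f^a baseline (default 1).
#' @param pink_noise_power_uv2 total broadband power of the pink baseline
#'   (0 disables it).
#' @param artifact_rate_per_min expected muscle-burst count per minute
#'   (100 ms transients on both channels).
#' @param artifact_amplitude_uv burst peak amplitude (default 150, above the
#'   +-100 segment rejection threshold).
#' @param alpha_peak_power_uv2 power of a concentrated oscillation at
#'   `iaf_hz` (counted toward the upper-alpha band's target); makes the
#'   alpha peak sharp, as in resting EEG.
#' @param alpha_flank_sd_hz spectral width of the alpha peak flanks in Hz.
#' @param seed integer seed for phases and artifact times.
#' @return a list of class `rest_spectrum_params`.
#' @export
rest_spectrum_params <- function(iaf_hz = 10,
                                 band_power_targets = c(
                                   theta = 20, lower1_alpha = 18,
                                   lower2_alpha = 22, upper_alpha = 22, beta = 12
                                 ),
                                 pink_noise_exponent = 1,
                                 pink_noise_power_uv2 = 15,
                                 artifact_rate_per_min = 0,
                                 artifact_amplitude_uv = 150,
                                 alpha_peak_power_uv2 = 8,
                                 alpha_flank_sd_hz = 1.2,
                                 seed = 1L) {
  check_scalar_number(iaf_hz, "iaf_hz", 8, 13)
  if (!identical(sort(names(band_power_targets)), sort(band_names())) ||
    any(band_power_targets < 0)) {
    stop_totonou("band_power_targets must name exactly the five analysis bands", "bad_parameter")
  }
  check_scalar_number(pink_noise_power_uv2, "pink_noise_power_uv2", lower = 0)
  check_scalar_number(artifact_rate_per_min, "artifact_rate_per_min", lower = 0)
  structure(
    list(
      iaf_hz = iaf_hz,
      band_power_targets = band_power_targets[band_names()],
      pink_noise_exponent = pink_noise_exponent,
      pink_noise_power_uv2 = pink_noise_power_uv2,
      artifact_rate_per_min = artifact_rate_per_min,
      artifact_amplitude_uv = artifact_amplitude_uv,
      alpha_peak_power_uv2 = alpha_peak_power_uv2,
      alpha_flank_sd_hz = alpha_flank_sd_hz,
      seed = seed
    ),
    class = "rest_spectrum_params"
  )
}

#' Generate a pseudorandom oddball stimulus sequence
#'
#' Emits `n_total` stimuli of which `round(n_total * target_fraction)` are
#' targets, with at least `min_standards_between` standards between any two
#' consecutive targets (the study uses 200 stimuli, 20% targets, gap >= 2).
#' The surplus standards are distributed uniformly at random over the slots
#' around the targets; output is deterministic given `seed`.
#'
#' @param n_total total number of stimuli.
#' @param target_fraction fraction of targets in `[0, 1)`.
#' @param min_standards_between minimum number of standards between targets.
#' @param seed integer seed.
#' @return character vector of `"standard"` / `"target"`.
#' @export
generate_stimulus_sequence <- function(n_total, target_fraction,
                                       min_standards_between = 2, seed = 1L) {
  check_scalar_number(n_total, "n_total", lower = 1)
  check_scalar_number(target_fraction, "target_fraction", 0, 1 - 1e-12)
  check_scalar_number(min_standards_between, "min_standards_between", lower = 0)
  n_total <- as.integer(n_total)
  n_tgt <- as.integer(round(n_total * target_fraction))
  if (n_tgt == 0L) return(rep("standard", n_total))
  need <- n_tgt + max(n_tgt - 1L, 0L) * min_standards_between
  if (need > n_total) {
    stop_totonou("infeasible sequence: too many targets for the gap constraint", "infeasible_sequence")
  }
  extras <- n_total - need
  slots <- n_tgt + 1L # before first target, between targets, after last
  counts <- with_seed(seed, {
    if (extras > 0L) tabulate(sample.int(slots, extras, replace = TRUE), nbins = slots) else integer(slots)
  })
  out <- character(0)
  for (i in seq_len(n_tgt)) {
    gap <- if (i == 1L) 0L else min_standards_between
    out <- c(out, rep("standard", gap + counts[i]), "target")
  }
  c(out, rep("standard", counts[slots]))
}

# unit-variance 1/f^a noise via frequency-domain shaping
pink_noise <- function(n, rate_hz, exponent) {
  nk <- n %/% 2L
  f <- (1:nk) * rate_hz / n
  amp <- f^(-exponent / 2)
  ph <- stats::runif(nk, 0, 2 * pi)
  xk <- complex(modulus = amp, argument = ph)
  spec <- complex(real = rep(0, n))
  spec[2:(nk + 1L)] <- xk
  spec[n:(n - nk + 2L)] <- Conj(xk[1:(nk - 1L)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.numeric(x / stats::sd(x))
}

#' Simulate one oddball session
#'
#' Builds a 500 Hz (by default) four-channel recording (Fz, Cz, Pz, EOG).
#' Target epochs carry the Gaussian MMN and P300 deflections on the scalp
#' channels; standard epochs carry background noise only. Blinks are 300 ms
#' half-sine transients on EOG (20% bleed into the scalp channels) at the
#' configured rate; their onset times are attached as attribute
#' `"blink_onsets_s"`. Simulated response times are log-normal with the given
#' median and recorded on correct target markers.
#'
#' @param sequence stimulus sequence from [generate_stimulus_sequence()].
#' @param shape an `erp_shape_params`.
#' @param rate_hz sampling rate (default 500).
#' @param soa_s stimulus onset asynchrony in seconds (default 1.5).
#' @param seed integer seed; identical seeds yield bit-identical output.
#' @param rt_median_ms median simulated reaction time.
#' @param rt_sdlog log-sd of the reaction-time distribution.
#' @param response_accuracy probability a target receives a correct response.
#' @return list with `recording` (an `eeg_recording`) and `markers`
#'   (an `event_markers` table).
#' @export
simulate_oddball_recording <- function(sequence, shape = erp_shape_params(),
                                       rate_hz = 500, soa_s = 1.5, seed = 1L,
                                       rt_median_ms = 400, rt_sdlog = 0.15,
                                       response_accuracy = 0.95) {
  stopifnot(inherits(shape, "erp_shape_params"))
  n_stim <- length(sequence)
  if (n_stim < 1L) stop_totonou("empty stimulus sequence", "bad_parameter")
  duration_s <- n_stim * soa_s + 1
  n <- as.integer(round(duration_s * rate_hz))
  channels <- c("Fz", "Cz", "Pz", "EOG")
  with_seed(seed, {
    samples <- matrix(0, 4L, n)
    if (shape$background_noise_sd_uv > 0) {
      for (ch in 1:4) {
        samples[ch, ] <- shape$background_noise_sd_uv *
          (sqrt(0.5) * pink_noise(n, rate_hz, 1) + sqrt(0.5) * stats::rnorm(n))
      }
    }
    # ERP kernel over the post-stimulus second
    kt <- (0:as.integer(round(0.6 * rate_hz))) / rate_hz * 1000 # ms
    kernel <- shape$mmn_amplitude_uv *
      exp(-(kt - shape$mmn_latency_ms)^2 / (2 * shape$component_width_ms^2)) +
      shape$p300_amplitude_uv *
        exp(-(kt - shape$p300_latency_ms)^2 / (2 * shape$component_width_ms^2))
    onsets <- as.integer(round((seq_len(n_stim) - 1L) * soa_s * rate_hz))
    for (i in which(sequence == "target")) {
      idx <- onsets[i] + seq_along(kt) # 1-based sample positions
      samples[1:3, idx] <- sweep(samples[1:3, idx, drop = FALSE], 2L, kernel, "+")
    }
    # blinks
    n_blink <- as.integer(round(shape$blink_rate_per_min * duration_s / 60))
    blink_onsets <- sort(stats::runif(n_blink, 0, duration_s - 0.4))
    blen <- as.integer(round(0.3 * rate_hz))
    bshape <- shape$blink_amplitude_uv * sin(pi * (seq_len(blen) - 0.5) / blen)
    for (b in blink_onsets) {
      idx <- as.integer(round(b * rate_hz)) + seq_len(blen)
      samples[4L, idx] <- samples[4L, idx] + bshape
      samples[1:3, idx] <- samples[1:3, idx, drop = FALSE] +
        matrix(0.2 * bshape, 3L, blen, byrow = TRUE)
    }
    # responses
    is_tgt <- sequence == "target"
    correct <- rep(NA, n_stim)
    rt <- rep(NA_real_, n_stim)
    correct[is_tgt] <- stats::runif(sum(is_tgt)) < response_accuracy
    n_ok <- sum(correct[is_tgt])
    rt[is_tgt][correct[is_tgt]] <- pmax(
      150, stats::rlnorm(n_ok, meanlog = log(rt_median_ms), sdlog = rt_sdlog)
    )
    rec <- new_recording(samples, rate_hz, channels)
    attr(rec, "blink_onsets_s") <- blink_onsets
    markers <- new_event_markers(onsets, sequence, rt, correct, n_samples = n)
    list(recording = rec, markers = markers)
  })
}

#' Simulate a two-channel in-ear rest recording
#'
#' Frequency-domain synthesis: random-phase components whose one-sided power
#' follows a pink baseline plus the five band shapes of
#' [rest_spectrum_params()], each band rescaled so its realised power equals
#' its target exactly (pink contribution included). Channels L and R receive
#' independent phases. Muscle-burst artifacts (100 ms, above the segment
#' rejection threshold) are inserted at the configured rate; onset times are
#' attached as attribute `"artifact_onsets_s"`.
#'
#' @param duration_s recording length in seconds (>= one 8 s analysis
#'   segment).
#' @param params a `rest_spectrum_params`.
#' @param rate_hz sampling rate (default 600).
#' @return an `eeg_recording` with channels L and R.
#' @export
simulate_inear_rest <- function(duration_s, params = rest_spectrum_params(),
                                rate_hz = 600) {
  stopifnot(inherits(params, "rest_spectrum_params"))
  check_scalar_number(duration_s, "duration_s", lower = 8)
  n <- as.integer(round(duration_s * rate_hz))
  nk <- n %/% 2L
  f <- (1:nk) * rate_hz / n
  # per-bin power targets
  p_bin <- rep(0, nk)
  if (params$pink_noise_power_uv2 > 0) {
    w <- ifelse(f >= 0.5, f^(-params$pink_noise_exponent), 0)
    p_bin <- params$pink_noise_power_uv2 * w / sum(w)
  }
  if (params$alpha_peak_power_uv2 > 0) {
    j <- which.min(abs(f - params$iaf_hz))
    p_bin[j] <- p_bin[j] + params$alpha_peak_power_uv2
  }
  edges <- band_edges(params$iaf_hz)
  for (b in rownames(edges)) {
    inside <- f >= edges[b, "lo"] & f < edges[b, "hi"]
    if (!any(inside)) next
    s <- if (b %in% c("lower2_alpha", "upper_alpha")) {
      exp(-(f[inside] - params$iaf_hz)^2 / (2 * params$alpha_flank_sd_hz^2))
    } else {
      rep(1, sum(inside))
    }
    surplus <- params$band_power_targets[[b]] - sum(p_bin[inside])
    if (surplus > 0) p_bin[inside] <- p_bin[inside] + surplus * s / sum(s)
  }
  with_seed(params$seed, {
    samples <- matrix(0, 2L, n)
    for (ch in 1:2) {
      ph <- stats::runif(nk, 0, 2 * pi)
      xk <- complex(modulus = n * sqrt(p_bin / 2), argument = ph)
      spec <- complex(real = rep(0, n))
      spec[2:(nk + 1L)] <- xk
      spec[n:(n - nk + 2L)] <- Conj(xk[1:(nk - 1L)])
      samples[ch, ] <- Re(stats::fft(spec, inverse = TRUE)) / n
    }
    n_art <- as.integer(round(params$artifact_rate_per_min * duration_s / 60))
    art_onsets <- sort(stats::runif(n_art, 0, duration_s - 0.2))
    alen <- as.integer(round(0.1 * rate_hz))
    ashape <- params$artifact_amplitude_uv * sin(pi * (seq_len(alen) - 0.5) / alen)
    for (a in art_onsets) {
      idx <- as.integer(round(a * rate_hz)) + seq_len(alen)
      samples[, idx] <- samples[, idx, drop = FALSE] +
        matrix(ashape, 2L, alen, byrow = TRUE)
    }
    rec <- new_recording(samples, rate_hz, c("L", "R"))
    attr(rec, "artifact_onsets_s") <- art_onsets
    rec
  })
}

default_stage_effect <- function() {
  one <- stats::setNames(rep(1, 5), band_names())
  list(
    pre = one,
    post1 = c(theta = 1.9, lower1_alpha = 1.8, lower2_alpha = 1.05, upper_alpha = 1.05, beta = 1),
    post2 = c(theta = 2.1, lower1_alpha = 2.0, lower2_alpha = 1.9, upper_alpha = 1.9, beta = 1),
    post3 = c(theta = 2.2, lower1_alpha = 2.1, lower2_alpha = 2.0, upper_alpha = 2.0, beta = 1)
  )
}

default_erp_stage_effect <- function() {
  list(post3 = c(mmn_amplitude_uv = -3, p300_amplitude_uv = -2.5))
}

#' Design of a synthetic two-group cohort
#'
#' Describes the study layout the generator emulates: a sauna group and a
#' control group, four sets (pre, post1, post2, post3) of in-ear rest,
#' oddball sessions at pre and post3, and questionnaire scores coupled to
#' each participant's theta-power change. The sauna group receives the
#' band-power stage factors and ERP deltas; the control group receives
#' identity effects.
#'
#' @param n_per_group participants per group (the study used 10).
#' @param stage_effect list mapping each stage to a named 5-vector of
#'   multiplicative band-power factors (pre must be all 1). The default
#'   mirrors the reported direction: theta and lower1 alpha rise from the
#'   first set, lower2 and upper alpha from the second, beta stays flat.
#' @param erp_stage_effect list mapping stages to additive deltas on
#'   `mmn_amplitude_uv` / `p300_amplitude_uv` for the sauna group (default:
#'   at post3 the MMN deepens by 3 microvolts and the P300 shrinks by 2.5).
#' @param score_coupling correlation between a participant's theta-power
#'   change and the designated questionnaire items (Q2, Q4, Q14).
#' @param rest_duration_s length of each in-ear rest recording in seconds.
#' @param oddball_n_stimuli,target_fraction,min_standards_between oddball
#'   task layout (defaults: 200 stimuli, 20% targets, gap >= 2).
#' @param subject_sdlog between-participant log-sd of band power.
#' @param stage_noise_sdlog within-participant (stage-to-stage) log-sd.
#' @param rt_stage_shift_ms additive shift of the sauna group's median RT at
#'   post3 (negative = faster).
#' @param erp_noise_sd_uv scalp background noise sd.
#' @param blink_rate_per_min scalp blink rate.
#' @param artifact_rate_per_min in-ear muscle-burst rate.
#' @param base_band_power named 5-vector of pre-stage band-power targets.
#' @param scalp_rate_hz,inear_rate_hz device sampling rates.
#' @param seed master seed; the whole cohort is a deterministic function
#'   of it.
#' @return a list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 10,
                          stage_effect = default_stage_effect(),
                          erp_stage_effect = default_erp_stage_effect(),
                          score_coupling = 0.77,
                          rest_duration_s = 80,
                          oddball_n_stimuli = 200,
                          target_fraction = 0.2,
                          min_standards_between = 2,
                          subject_sdlog = 0.2,
                          stage_noise_sdlog = 0.1,
                          rt_stage_shift_ms = -40,
                          erp_noise_sd_uv = 8,
                          blink_rate_per_min = 2,
                          artifact_rate_per_min = 0.5,
                          base_band_power = c(
                            theta = 20, lower1_alpha = 18,
                            lower2_alpha = 22, upper_alpha = 22, beta = 12
                          ),
                          scalp_rate_hz = 500, inear_rate_hz = 600,
                          seed = 1L) {
  check_scalar_number(n_per_group, "n_per_group", lower = 1)
  check_scalar_number(score_coupling, "score_coupling", -1, 1)
  stages <- c("pre", "post1", "post2", "post3")
  if (!identical(sort(names(stage_effect)), sort(stages))) {
    stop_totonou("stage_effect must name stages pre, post1, post2, post3", "bad_parameter")
  }
  if (any(abs(stage_effect$pre - 1) > 1e-12)) {
    stop_totonou("stage_effect$pre must be the identity factor 1.0", "bad_parameter")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group), stage_effect = stage_effect,
      erp_stage_effect = erp_stage_effect, score_coupling = score_coupling,
      rest_duration_s = rest_duration_s, oddball_n_stimuli = oddball_n_stimuli,
      target_fraction = target_fraction, min_standards_between = min_standards_between,
      subject_sdlog = subject_sdlog, stage_noise_sdlog = stage_noise_sdlog,
      rt_stage_shift_ms = rt_stage_shift_ms, erp_noise_sd_uv = erp_noise_sd_uv,
      blink_rate_per_min = blink_rate_per_min,
      artifact_rate_per_min = artifact_rate_per_min,
      base_band_power = base_band_power,
      scalp_rate_hz = scalp_rate_hz, inear_rate_hz = inear_rate_hz,
      seed = seed
    ),
    class = "cohort_design"
  )
}

questionnaire_items <- function() paste0("Q", 1:29)
coupled_items <- function() c("Q2", "Q4", "Q14")

#' Simulate a full synthetic cohort
#'
#' Generates, per participant: in-ear rest recordings for pre/post1/post2/
#' post3, oddball sessions (recording + markers) for pre and post3, and
#' questionnaire scores for all 29 items at every stage with the designated
#' items (Q2, Q4, Q14) coupled to the participant's injected theta-power
#' change at strength `design$score_coupling`. Sauna participants receive
#' the design's stage effects; controls receive identity effects. The whole
#' cohort is a deterministic function of `design$seed`.
#'
#' @param design a `cohort_design`.
#' @param out_dir optional directory; when given the cohort is also written
#'   to disk as a session tree ([write_cohort()]).
#' @param modalities which data streams to synthesise (any of `"inear"`,
#'   `"oddball"`, `"scores"`; default all). The injected band-power targets
#'   (`truth`) are always produced.
#' @return a `totonou_cohort`: list with `participants`, `inear`
#'   (`[[participant]][[stage]]` recordings), `oddball`
#'   (`[[participant]][[stage]]` recording + markers), `scores`, and `truth`
#'   (the injected per-recording band-power targets, IAFs and ERP
#'   amplitudes, for generator-recovery tests).
#' @export
simulate_cohort <- function(design = cohort_design(), out_dir = NULL,
                            modalities = c("inear", "oddball", "scores")) {
  stopifnot(inherits(design, "cohort_design"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  stages <- c("pre", "post1", "post2", "post3")
  n_tot <- 2L * design$n_per_group
  ids <- sprintf("P%02d", seq_len(n_tot))
  groups <- rep(c("sauna", "control"), each = design$n_per_group)
  participants <- data.frame(participant = ids, group = groups, stringsAsFactors = FALSE)

  inear <- list()
  oddball <- list()
  truth_rows <- list()
  theta_true <- matrix(0, n_tot, 2L, dimnames = list(ids, c("pre", "post3")))

  for (p in seq_len(n_tot)) {
    pid <- ids[p]
    sauna <- groups[p] == "sauna"
    pseed <- child_seed(design$seed, p)
    pdraws <- with_seed(pseed, list(
      iaf = stats::runif(1, 9, 11.5),
      mult = stats::rlnorm(5, 0, design$subject_sdlog),
      stage_eps = matrix(stats::rlnorm(20, 0, design$stage_noise_sdlog), 4L, 5L),
      erp_jit = stats::rlnorm(2, 0, 0.1)
    ))
    names(pdraws$mult) <- band_names()
    inear[[pid]] <- list()
    for (s in seq_along(stages)) {
      stage <- stages[s]
      fac <- if (sauna) design$stage_effect[[stage]] else stats::setNames(rep(1, 5), band_names())
      eps <- stats::setNames(pdraws$stage_eps[s, ], band_names())
      targets <- design$base_band_power[band_names()] * pdraws$mult * fac[band_names()] * eps
      rp <- rest_spectrum_params(
        iaf_hz = pdraws$iaf, band_power_targets = targets,
        artifact_rate_per_min = design$artifact_rate_per_min,
        alpha_peak_power_uv2 = 0.35 * targets[["upper_alpha"]],
        seed = child_seed(pseed, 10L + s)
      )
      if ("inear" %in% modalities) {
        inear[[pid]][[stage]] <- simulate_inear_rest(design$rest_duration_s, rp, design$inear_rate_hz)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        participant = pid, group = groups[p], stage = stage,
        band = band_names(), target_power_uv2 = unname(targets),
        iaf_hz = pdraws$iaf, stringsAsFactors = FALSE
      )
      if (stage %in% colnames(theta_true)) theta_true[pid, stage] <- targets[["theta"]]
    }
    oddball[[pid]] <- list()
    for (stage in if ("oddball" %in% modalities) c("pre", "post3") else character(0)) {
      mmn <- -5 * pdraws$erp_jit[1L]
      p3 <- 6 * pdraws$erp_jit[2L]
      rt_med <- 400
      if (sauna && !is.null(design$erp_stage_effect[[stage]])) {
        d <- design$erp_stage_effect[[stage]]
        mmn <- mmn + (d[["mmn_amplitude_uv"]] %||% 0)
        p3 <- max(0, p3 + (d[["p300_amplitude_uv"]] %||% 0))
        rt_med <- rt_med + design$rt_stage_shift_ms
      }
      shape <- erp_shape_params(
        mmn_amplitude_uv = min(mmn, 0), p300_amplitude_uv = p3,
        background_noise_sd_uv = design$erp_noise_sd_uv,
        blink_rate_per_min = design$blink_rate_per_min
      )
      sseed <- child_seed(pseed, if (stage == "pre") 20L else 23L)
      seqn <- generate_stimulus_sequence(
        design$oddball_n_stimuli, design$target_fraction,
        design$min_standards_between, sseed
      )
      oddball[[pid]][[stage]] <- simulate_oddball_recording(
        seqn, shape,
        rate_hz = design$scalp_rate_hz, seed = child_seed(sseed, 1L),
        rt_median_ms = rt_med
      )
    }
  }

  # questionnaire scores: designated items track the theta change
  dtheta <- theta_true[, "post3"] - theta_true[, "pre"]
  z <- stats::ave(dtheta, groups, FUN = function(v) {
    if (length(v) > 1L && stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  })
  rho <- design$score_coupling
  scores <- if (!"scores" %in% modalities) NULL else with_seed(child_seed(design$seed, 999L), {
    rows <- list()
    for (p in seq_len(n_tot)) {
      for (item in questionnaire_items()) {
        base <- stats::runif(1, 20, 40)
        if (item %in% coupled_items()) {
          delta <- 25 * (rho * z[p] + sqrt(max(0, 1 - rho^2)) * stats::rnorm(1))
        } else {
          delta <- stats::rnorm(1, 0, 8)
        }
        vals <- pmin(100, pmax(0, base + delta * c(0, 1, 2, 3) / 3 + stats::rnorm(4, 0, 2)))
        rows[[length(rows) + 1L]] <- data.frame(
          participant = ids[p], group = groups[p], stage = stages,
          item = item, value = vals, stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })

  cohort <- structure(
    list(
      design = design, participants = participants,
      inear = inear, oddball = oddball, scores = scores,
      truth = do.call(rbind, truth_rows)
    ),
    class = "totonou_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.totonou_cohort <- function(x, ...) {
  cat(sprintf(
    "<totonou_cohort> %d participants (%d per group), stages pre/post1/post2/post3\n",
    nrow(x$participants), x$design$n_per_group
  ))
  invisible(x)
}

#' Write a cohort as an on-disk session tree
#'
#' Layout: `participants.tsv` and `scores.tsv` at the root, one directory per
#' participant containing `inear_<stage>` and `oddball_<stage>` recordings
#' (delimited dialect with YAML sidecars) plus `oddball_<stage>.events.tsv`.
#'
#' @param cohort a `totonou_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "totonou_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(cohort$participants, file.path(dir, "participants.tsv"))
  if (!is.null(cohort$scores)) write_table(cohort$scores, file.path(dir, "scores.tsv"))
  for (pid in cohort$participants$participant) {
    pd <- file.path(dir, pid)
    dir.create(pd, showWarnings = FALSE)
    for (stage in names(cohort$inear[[pid]])) {
      write_recording(cohort$inear[[pid]][[stage]], file.path(pd, sprintf("inear_%s.tsv", stage)))
    }
    for (stage in names(cohort$oddball[[pid]])) {
      sess <- cohort$oddball[[pid]][[stage]]
      write_recording(sess$recording, file.path(pd, sprintf("oddball_%s.tsv", stage)))
      write_events(sess$markers, file.path(pd, sprintf("oddball_%s.events.tsv", stage)))
    }
  }
  invisible(dir)
}

#' Read a cohort session tree written by [write_cohort()]
#'
#' @param dir the cohort directory.
#' @return a `totonou_cohort` (without the generator's `truth` table, which
#'   only exists for in-memory cohorts).
#' @export
read_cohort <- function(dir) {
  participants <- read_table(file.path(dir, "participants.tsv"))
  sf <- file.path(dir, "scores.tsv")
  scores <- if (file.exists(sf)) read_table(sf) else NULL
  inear <- list()
  oddball <- list()
  for (pid in participants$participant) {
    pd <- file.path(dir, pid)
    inear[[pid]] <- list()
    oddball[[pid]] <- list()
    for (stage in c("pre", "post1", "post2", "post3")) {
      f <- file.path(pd, sprintf("inear_%s.tsv", stage))
      if (file.exists(f)) inear[[pid]][[stage]] <- read_recording(f)
      g <- file.path(pd, sprintf("oddball_%s.tsv", stage))
      if (file.exists(g)) {
        oddball[[pid]][[stage]] <- list(
          recording = read_recording(g),
          markers = read_events(file.path(pd, sprintf("oddball_%s.events.tsv", stage)))
        )
      }
    }
  }
  structure(
    list(
      design = NULL, participants = participants,
      inear = inear, oddball = oddball, scores = scores, truth = NULL
    ),
    class = "totonou_cohort"
  )
}
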