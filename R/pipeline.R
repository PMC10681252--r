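# Cohort-level pipelines: from a session tree (in memory or on disk) to the
# band-power table, the ERP/RT tables, the set-effect statistics and the
# decoder report.

stages_all <- function() c("pre", "post1", "post2", "post3")

#' Band-power table for a cohort
#'
#' The in-ear spectral path: each rest recording is band-pass filtered
#' (2-30 Hz), cut into 8 s segments, amplitude-screened at +-100 microvolts,
#' and transformed to per-segment Hann periodograms. Each participant's IAF
#' is estimated from the pre-stage spectra (8-13 Hz peak of the segment- and
#' channel-averaged power) and anchors the five band intervals for all of
#' that participant's stages.
#'
#' @param cohort a `totonou_cohort`.
#' @param filter_band in-ear filter cutoffs (default `c(2, 30)`).
#' @param segment_s segment length in seconds (default 8).
#' @param reject_threshold_uv segment rejection threshold (default 100).
#' @return a `data.frame` with one row per participant x stage x channel x
#'   band: `power_uv2` and the participant's `iaf_hz`.
#' @export
cohort_band_powers <- function(cohort, filter_band = c(2, 30), segment_s = 8,
                               reject_threshold_uv = 100) {
  stopifnot(inherits(cohort, "totonou_cohort"))
  rows <- list()
  for (pid in cohort$participants$participant) {
    grp <- cohort$participants$group[cohort$participants$participant == pid]
    spectra <- list()
    for (stage in intersect(stages_all(), names(cohort$inear[[pid]]))) {
      rec <- cohort$inear[[pid]][[stage]]
      require_channels(rec, c("L", "R"))
      rec <- bandpass(rec, filter_band[1L], filter_band[2L])
      segs <- reject_segments(segment_recording(rec, segment_s), reject_threshold_uv)
      spectra[[stage]] <- power_spectrum(segs)
    }
    if (is.null(spectra$pre)) {
      stop_totonou(sprintf("participant %s lacks a pre-stage recording", pid), "missing_cells")
    }
    iaf <- estimate_iaf(spectra$pre)
    for (stage in names(spectra)) {
      bp <- band_powers(spectra[[stage]], iaf)
      bp$participant <- pid
      bp$group <- grp
      bp$stage <- stage
      rows[[length(rows) + 1L]] <- bp
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("participant", "group", "stage", "channel", "band", "power_uv2", "iaf_hz")]
}

#' Set-effect statistics for one band and channel
#'
#' Runs the two-way mixed ANOVA (group x set) on one band's power for one
#' in-ear channel, the per-group simple main effects of set, and -- within
#' the sauna group -- Holm-Bonferroni pairwise comparisons of the four sets
#' using the pooled within-subject error.
#'
#' @param bp a band-power table from [cohort_band_powers()].
#' @param band one of [band_names()].
#' @param channel `"L"` or `"R"`.
#' @return list with `anova` (a `mixed_anova_result`), `simple_effects`, and
#'   `pairwise_sauna`.
#' @export
band_power_stats <- function(bp, band, channel = "L") {
  d <- bp[bp$band == band & bp$channel == channel, ]
  if (nrow(d) == 0L) stop_totonou("no rows for that band/channel", "bad_parameter")
  an <- mixed_anova(data.frame(
    participant = d$participant, group = d$group,
    level = factor(d$stage, levels = stages_all()), value = d$power_uv2
  ))
  sme <- simple_main_effects(an)
  sauna_means <- an$cell_means["sauna", ]
  pw <- holm_pairwise(sauna_means, an$ms_error_within, an$n_per_group, an$df_error_within)
  list(anova = an, simple_effects = sme, pairwise_sauna = pw)
}

#' Significance pattern of set effects across the five bands
#'
#' For each band (on one channel): if the simple main effect of set within
#' the sauna group is significant, the Holm-adjusted pre-vs-post contrasts
#' are reported; a band with no significant simple main effect reports all
#' contrasts as non-significant. This is the summary the study tabulates per
#' band and set pair.
#'
#' @param bp a band-power table from [cohort_band_powers()].
#' @param channel `"L"` (default) or `"R"`.
#' @param alpha significance level (default 0.05).
#' @return logical matrix, bands x contrasts
#'   (`pre_post1`, `pre_post2`, `pre_post3`).
#' @export
set_effect_pattern <- function(bp, channel = "L", alpha = 0.05) {
  contrasts <- c("pre_post1", "pre_post2", "pre_post3")
  out <- matrix(FALSE, length(band_names()), length(contrasts),
    dimnames = list(band_names(), contrasts)
  )
  for (b in band_names()) {
    st <- band_power_stats(bp, b, channel)
    sme_sauna <- st$simple_effects[st$simple_effects$group == "sauna", ]
    if (!sme_sauna$significant) next
    pw <- st$pairwise_sauna
    for (k in 1:3) {
      row <- pw$level_a == "pre" & pw$level_b == paste0("post", k)
      out[b, k] <- any(pw$significant[row])
    }
  }
  out
}

#' ERP measure table for a cohort
#'
#' The scalp oddball path: each session is band-pass filtered (0.1-30 Hz),
#' epoched from -100 to 600 ms with baseline correction, amplitude-screened
#' at +-50 microvolts (EOG included), averaged per condition, and scored for
#' MMN and P300 on the difference waveform.
#'
#' @param cohort a `totonou_cohort`.
#' @param filter_band scalp filter cutoffs (default `c(0.1, 30)`).
#' @param reject_threshold_uv epoch rejection threshold (default 50).
#' @param measure `"area"` or `"peak"` (see [erp_measures()]).
#' @return a `data.frame` with one row per participant x stage x channel.
#' @export
cohort_erp_table <- function(cohort, filter_band = c(0.1, 30),
                             reject_threshold_uv = 50,
                             measure = c("area", "peak")) {
  measure <- match.arg(measure)
  stopifnot(inherits(cohort, "totonou_cohort"))
  rows <- list()
  for (pid in names(cohort$oddball)) {
    grp <- cohort$participants$group[cohort$participants$participant == pid]
    for (stage in names(cohort$oddball[[pid]])) {
      sess <- cohort$oddball[[pid]][[stage]]
      require_channels(sess$recording, c("Fz", "Cz", "Pz"))
      rec <- bandpass(sess$recording, filter_band[1L], filter_band[2L])
      eps <- epoch_recording(rec, sess$markers)
      eps <- lapply(eps, reject_epochs, threshold_uv = reject_threshold_uv)
      res <- erp_measures(eps, measure = measure)
      sc <- res$scores[res$scores$channel %in% c("Fz", "Cz", "Pz"), ]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, group = grp, stage = stage,
        channel = sc$channel, mmn = sc$mmn, p300 = sc$p300,
        mmn_area = sc$mmn_area, p300_area = sc$p300_area,
        n_standard = res$n_epochs_used[["standard"]],
        n_target = res$n_epochs_used[["target"]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reaction-time table for a cohort
#'
#' @param cohort a `totonou_cohort`.
#' @return a `data.frame` with one row per participant x stage: mean/sd of
#'   correct-response RTs and the correct-response count.
#' @export
cohort_rt_table <- function(cohort) {
  stopifnot(inherits(cohort, "totonou_cohort"))
  rows <- list()
  for (pid in names(cohort$oddball)) {
    grp <- cohort$participants$group[cohort$participants$participant == pid]
    for (stage in names(cohort$oddball[[pid]])) {
      s <- rt_summary(cohort$oddball[[pid]][[stage]]$markers)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant = pid, group = grp, stage = stage, stringsAsFactors = FALSE), s
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decoder feature matrix for a cohort
#'
#' Collects every in-ear rest recording of the selected participants into
#' the decoder's session list and builds the 219-column feature matrix.
#'
#' @param cohort a `totonou_cohort`.
#' @param group restrict to one group (default `"sauna"`, the group the
#'   study decodes); `NULL` uses everyone.
#' @param ... passed to [build_features()].
#' @return a `feature_matrix`.
#' @export
cohort_features <- function(cohort, group = "sauna", ...) {
  stopifnot(inherits(cohort, "totonou_cohort"))
  pids <- cohort$participants$participant
  if (!is.null(group)) pids <- pids[cohort$participants$group %in% group]
  sessions <- list()
  for (pid in pids) {
    for (stage in names(cohort$inear[[pid]])) {
      sessions[[length(sessions) + 1L]] <- list(
        recording = cohort$inear[[pid]][[stage]],
        participant = pid, stage = stage
      )
    }
  }
  build_features(sessions, ...)
}

#' Correlation of band-power change with questionnaire-score change
#'
#' Pearson correlation between each participant's post3-minus-pre change in
#' one band's power (averaged over L and R) and the post3-minus-pre change
#' of each questionnaire item, within one group.
#'
#' @param bp a band-power table from [cohort_band_powers()].
#' @param scores a cohort score table (`participant`, `stage`, `item`,
#'   `value`).
#' @param band band to correlate (default `"theta"`).
#' @param items questionnaire items (default: all present).
#' @param group group to analyse (default `"sauna"`).
#' @return a `data.frame` with one row per item: `r`, `p`, `n`.
#' @export
score_change_correlation <- function(bp, scores, band = "theta",
                                     items = NULL, group = "sauna") {
  d <- bp[bp$band == band & bp$group == group, ]
  agg <- stats::aggregate(power_uv2 ~ participant + stage, d, mean)
  wide <- stats::reshape(agg,
    idvar = "participant", timevar = "stage", direction = "wide"
  )
  delta <- wide$power_uv2.post3 - wide$power_uv2.pre
  names(delta) <- wide$participant
  sc <- scores[scores$participant %in% names(delta), ]
  if (is.null(items)) items <- unique(sc$item)
  rows <- lapply(items, function(it) {
    si <- sc[sc$item == it, ]
    w <- stats::reshape(si[, c("participant", "stage", "value")],
      idvar = "participant", timevar = "stage", direction = "wide"
    )
    ds <- w$value.post3 - w$value.pre
    names(ds) <- w$participant
    common <- intersect(names(delta), names(ds))
    ct <- pearson_change_correlation(delta[common], ds[common])
    data.frame(item = it, r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
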