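# The synthetic-data generator: stimulus sequences, oddball sessions,
# in-ear rest spectra, and whole cohorts.

test_that("stimulus sequences respect counts and the minimum-gap constraint", {
  sq <- generate_stimulus_sequence(200, 0.20, 2, seed = 42)
  expect_true(validate_sequence(sq, 200, 40, 2))

  expect_equal(generate_stimulus_sequence(10, 0, 2, seed = 1), rep("standard", 10))

  # exhaustive check over many seeds on a small feasible problem
  for (s in 0:99) {
    expect_true(validate_sequence(generate_stimulus_sequence(8, 0.25, 2, seed = s), 8, 2, 2))
  }

  expect_error(
    generate_stimulus_sequence(8, 0.5, 3, seed = 1),
    class = "totonou_error_infeasible_sequence"
  )
  expect_identical(
    generate_stimulus_sequence(50, 0.2, 2, seed = 7),
    generate_stimulus_sequence(50, 0.2, 2, seed = 7)
  )
})

test_that("noiseless oddball sessions carry the injected deflections exactly", {
  sq <- generate_stimulus_sequence(30, 0.2, 2, seed = 3)
  shape <- erp_shape_params(
    mmn_amplitude_uv = -5, p300_amplitude_uv = 6,
    background_noise_sd_uv = 0, blink_rate_per_min = 0
  )
  sess <- simulate_oddball_recording(sq, shape, seed = 1)
  eps <- epoch_recording(sess$recording, sess$markers)
  res <- erp_measures(eps)
  w <- res$difference["Cz", ]
  # the 2 ms sample grid can sit one sample off the exact peak latency
  expect_equal(min(w), -5, tolerance = 5e-3)
  expect_lte(abs(res$times_ms[which.min(w)] - 175), 2)
  expect_equal(max(w), 6, tolerance = 5e-3)
  # standards carry no deflection
  expect_lt(max(abs(res$standard_avg)), 1e-9)
})

test_that("oddball simulation is bit-identical under the same seed", {
  sq <- generate_stimulus_sequence(20, 0.2, 2, seed = 2)
  shape <- erp_shape_params()
  a <- simulate_oddball_recording(sq, shape, seed = 99)
  b <- simulate_oddball_recording(sq, shape, seed = 99)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(as.data.frame(a$markers), as.data.frame(b$markers))
  c_ <- simulate_oddball_recording(sq, shape, seed = 100)
  expect_false(identical(a$recording$samples, c_$recording$samples))
})

test_that("scheduled blinks trip the epoch rejection threshold", {
  sq <- generate_stimulus_sequence(40, 0.2, 2, seed = 5)
  shape <- erp_shape_params(
    background_noise_sd_uv = 0,
    blink_rate_per_min = 20, blink_amplitude_uv = 120
  )
  sess <- simulate_oddball_recording(sq, shape, seed = 8)
  expect_gt(length(attr(sess$recording, "blink_onsets_s")), 0)
  eps <- lapply(epoch_recording(sess$recording, sess$markers), reject_epochs,
    threshold_uv = 50
  )
  expect_gt(sum(!eps$standard$kept) + sum(!eps$target$kept), 0)
})

test_that("in-ear rest synthesis hits its band-power targets", {
  base <- c(theta = 20, lower1_alpha = 18, lower2_alpha = 22, upper_alpha = 22, beta = 12)
  doubled <- base
  doubled["theta"] <- 2 * base[["theta"]]
  ratios <- sapply(1:10, function(s) {
    get_theta <- function(tg) {
      p <- rest_spectrum_params(iaf_hz = 10, band_power_targets = tg, seed = s)
      rec <- simulate_inear_rest(32, p, 600)
      sp <- power_spectrum(segment_recording(rec, 8))
      bp <- band_powers(sp, 10)
      mean(bp$power_uv2[bp$band == "theta"])
    }
    get_theta(doubled) / get_theta(base)
  })
  expect_equal(mean(ratios), 2, tolerance = 0.2)
})

test_that("in-ear rest shows an alpha peak at the injected IAF", {
  p <- rest_spectrum_params(iaf_hz = 10.5, seed = 4)
  rec <- simulate_inear_rest(40, p, 600)
  sp <- power_spectrum(segment_recording(rec, 8))
  expect_lt(abs(estimate_iaf(sp) - 10.5), 0.5 + 1e-9)
  expect_error(simulate_inear_rest(4, p), class = "totonou_error_bad_parameter")
})

test_that("in-ear artifacts trip the segment rejection threshold", {
  p <- rest_spectrum_params(
    iaf_hz = 10, artifact_rate_per_min = 6,
    artifact_amplitude_uv = 150, seed = 2
  )
  rec <- simulate_inear_rest(40, p, 600)
  expect_gt(length(attr(rec, "artifact_onsets_s")), 0)
  segs <- reject_segments(segment_recording(rec, 8), threshold_uv = 100)
  expect_gt(sum(!segs$kept), 0)
})

test_that("in-ear synthesis is deterministic given the params seed", {
  p <- rest_spectrum_params(seed = 11)
  expect_identical(
    simulate_inear_rest(16, p)$samples,
    simulate_inear_rest(16, p)$samples
  )
})

test_that("cohorts are deterministic and degenerate sizes stay usable", {
  d <- cohort_design(n_per_group = 2, rest_duration_s = 16, seed = 6)
  a <- simulate_cohort(d, modalities = "inear")
  b <- simulate_cohort(d, modalities = "inear")
  expect_identical(a$inear$P01$post2$samples, b$inear$P01$post2$samples)
  expect_identical(a$truth, b$truth)

  # n_per_group = 1: a valid tree, but group statistics must refuse
  d1 <- cohort_design(n_per_group = 1, rest_duration_s = 16, seed = 3)
  co1 <- simulate_cohort(d1, modalities = "inear")
  bp1 <- cohort_band_powers(co1)
  expect_error(
    band_power_stats(bp1, "theta", "L"),
    class = "totonou_error_insufficient_replication"
  )
})

test_that("a cohort session tree round-trips through disk", {
  d <- cohort_design(n_per_group = 1, rest_duration_s = 16, oddball_n_stimuli = 10, seed = 9)
  dir <- withr::local_tempdir()
  co <- simulate_cohort(d, out_dir = dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  back <- read_cohort(dir)
  expect_equal(back$participants, co$participants)
  expect_lt(max(abs(back$inear$P01$pre$samples - co$inear$P01$pre$samples)), 1e-9)
  expect_equal(
    back$oddball$P01$pre$markers$sample_index,
    co$oddball$P01$pre$markers$sample_index
  )
  expect_equal(nrow(back$scores), nrow(co$scores))
})

test_that("identity stage effects leave the group-by-set interaction null", {
  # under the null the interaction should rarely be significant
  eye <- stats::setNames(rep(1, 5), band_names())
  d <- cohort_design(
    n_per_group = 6, rest_duration_s = 16, seed = 31,
    stage_effect = list(pre = eye, post1 = eye, post2 = eye, post3 = eye)
  )
  hits <- sapply(1:8, function(k) {
    dd <- d
    dd$seed <- 31 + k
    co <- simulate_cohort(dd, modalities = "inear")
    bp <- cohort_band_powers(co)
    st <- band_power_stats(bp, "theta", "L")
    st$anova$interaction[["p"]] < 0.05
  })
  expect_lte(sum(hits), 2)
})
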