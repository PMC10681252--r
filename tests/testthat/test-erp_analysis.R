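# ERP averaging, component areas and reaction-time summaries.

test_that("average_erp is the pointwise mean over kept epochs only", {
  dat <- array(0, dim = c(2, 1, 350))
  dat[1, , ] <- 1
  dat[2, , ] <- 3
  es <- make_epoch_set(dat)
  expect_true(all(average_erp(es) == 2))

  es$kept[2] <- FALSE
  expect_true(all(average_erp(es) == 1))

  es$kept[] <- FALSE
  expect_error(average_erp(es), class = "totonou_error_no_usable_epochs")
})

test_that("averaging n noise epochs shrinks amplitude roughly as 1/sqrt(n)", {
  set.seed(7)
  n <- 40
  dat <- array(rnorm(n * 1 * 350), dim = c(n, 1, 350))
  es <- make_epoch_set(dat)
  ratio <- sd(average_erp(es)) / 1 # single-epoch sd is 1 by construction
  expect_gt(ratio, 0.5 / sqrt(n))
  expect_lt(ratio, 2 / sqrt(n))
})

test_that("component_area integrates the polarity-clipped waveform", {
  times <- seq(-100, 598, by = 2)
  zero <- rep(0, length(times))
  expect_equal(component_area(zero, times, c(100, 250), "negative"), 0)
  expect_equal(component_area(zero, times, c(240, 400), "positive"), 0)

  # closed-form Gaussian oracle: area = A * sigma * sqrt(2*pi)
  g <- -5 * exp(-(times - 175)^2 / (2 * 20^2))
  area <- component_area(g, times, c(100, 250), "negative")
  expect_equal(area, -5 * 20 * sqrt(2 * pi), tolerance = 0.03)

  # polarity clipping: an everywhere-positive waveform has zero MMN area
  pos <- rep(2, length(times))
  expect_equal(component_area(pos, times, c(100, 250), "negative"), 0)
  expect_gt(component_area(pos, times, c(240, 400), "positive"), 0)

  expect_error(
    component_area(zero, times, c(500, 700), "positive"),
    class = "totonou_error_window_outside_span"
  )
})

test_that("recovered component latency matches the injection within a sample", {
  sq <- generate_stimulus_sequence(30, 0.2, 2, seed = 21)
  shape <- erp_shape_params(
    mmn_latency_ms = 190, p300_latency_ms = 300,
    background_noise_sd_uv = 0, blink_rate_per_min = 0
  )
  sess <- simulate_oddball_recording(sq, shape, seed = 2)
  res <- erp_measures(epoch_recording(sess$recording, sess$markers))
  sc <- res$scores[res$scores$channel == "Fz", ]
  expect_lte(abs(sc$mmn_peak_latency_ms - 190), 2) # one sample at 500 Hz
  expect_lte(abs(sc$p300_peak_latency_ms - 300), 2)
})

test_that("p300 area grows monotonically with the injected amplitude", {
  sq <- generate_stimulus_sequence(20, 0.2, 2, seed = 5)
  areas <- sapply(c(2, 4, 6, 8), function(a) {
    shape <- erp_shape_params(
      p300_amplitude_uv = a,
      background_noise_sd_uv = 0, blink_rate_per_min = 0
    )
    sess <- simulate_oddball_recording(sq, shape, seed = 3)
    res <- erp_measures(epoch_recording(sess$recording, sess$markers))
    res$scores$p300_area[1]
  })
  expect_true(all(diff(areas) > 0))
})

test_that("the peak-amplitude measure switch reports extrema instead of areas", {
  sq <- generate_stimulus_sequence(20, 0.2, 2, seed = 5)
  shape <- erp_shape_params(background_noise_sd_uv = 0, blink_rate_per_min = 0)
  sess <- simulate_oddball_recording(sq, shape, seed = 3)
  eps <- epoch_recording(sess$recording, sess$markers)
  res <- erp_measures(eps, measure = "peak")
  # the 2 ms sample grid can miss the exact peak latency by one sample
  expect_equal(res$scores$mmn[1], -5, tolerance = 5e-3)
  expect_equal(res$scores$p300[1], 6, tolerance = 5e-3)
})

test_that("rt_summary uses correct target responses only", {
  mk <- new_event_markers(
    c(0, 750, 1500), c("standard", "target", "target"),
    response_time_ms = c(NA, 300, 500), responded_correctly = c(NA, TRUE, TRUE)
  )
  s <- rt_summary(mk)
  expect_equal(s$mean_rt_ms, 400)
  expect_equal(s$n_correct, 2L)

  mk2 <- new_event_markers(
    c(0, 750), c("target", "target"),
    response_time_ms = c(300, 900), responded_correctly = c(TRUE, FALSE)
  )
  s2 <- rt_summary(mk2)
  expect_equal(s2$mean_rt_ms, 300)
  expect_equal(s2$n_correct, 1L)

  mk3 <- new_event_markers(0, "target", response_time_ms = 400, responded_correctly = FALSE)
  expect_error(rt_summary(mk3), class = "totonou_error_no_correct_responses")
})

test_that("simulated RT stage shifts are recovered by the summary", {
  sq <- generate_stimulus_sequence(200, 0.2, 2, seed = 1)
  shape <- erp_shape_params()
  deltas <- sapply(1:6, function(s) {
    a <- simulate_oddball_recording(sq, shape, seed = s, rt_median_ms = 400)
    b <- simulate_oddball_recording(sq, shape, seed = 1000 + s, rt_median_ms = 360)
    rt_summary(b$markers)$mean_rt_ms - rt_summary(a$markers)$mean_rt_ms
  })
  expect_equal(mean(deltas), -40, tolerance = 0.5) # +- sampling error at ~6x38 RTs
})
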