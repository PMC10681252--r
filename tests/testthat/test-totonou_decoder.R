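# Feature construction, noise screen, balancing and the PCA + sparse
# discriminant decoding pipeline.

test_that("feature matrix has the 3 x 73 grid layout and stage-derived labels", {
  rec <- simulate_inear_rest(40, rest_spectrum_params(seed = 2), 600)
  fm <- build_features(list(
    list(recording = rec, participant = "P01", stage = "pre"),
    list(recording = rec, participant = "P01", stage = "post2")
  ))
  expect_equal(length(fm$grid_hz), 73L) # 4.0 .. 40.0 at 0.5 Hz
  expect_equal(range(fm$grid_hz), c(4, 40))
  expect_equal(ncol(fm$X), 219L)
  expect_equal(nrow(fm$X), 20L) # two 40 s sessions -> 10 segments each
  expect_equal(unique(fm$meta$class), c("non_totonou", "totonou"))
})

test_that("identical L and R channels null the difference-signal features", {
  x <- tiny_recording(n = 4800, rate = 600)$samples[1, ]
  rec <- new_recording(rbind(x, x), 600, c("L", "R"))
  fm <- build_features(list(list(recording = rec, participant = "P", stage = "pre")))
  dcols <- grepl("^D_", colnames(fm$X))
  expect_lt(max(fm$X[, dcols]), 1e-12)
  expect_gt(max(fm$X[, !dcols]), 0)
})

test_that("missing channels are a typed error", {
  rec <- new_recording(matrix(0, 1, 2400), 600, "L")
  expect_error(
    build_features(list(list(recording = rec, participant = "P", stage = "pre"))),
    class = "totonou_error_channel_mismatch"
  )
})

test_that("noise screen excludes exactly the high-power segments", {
  # all-equal rows: zero spread, keep everything
  fm0 <- make_fm(matrix(1, 10, 4), "P", rep(c("non_totonou", "totonou"), 5))
  expect_equal(nrow(noise_screen(fm0)$X), 10L)

  # one row with 10x the power among 50 -> exactly that row excluded
  set.seed(2)
  X <- matrix(abs(rnorm(50 * 6, mean = 5, sd = 0.1)), 50, 6)
  X[17, ] <- X[17, ] * 10
  fm <- make_fm(X, "P", rep(c("non_totonou", "totonou"), 25))
  out <- noise_screen(fm)
  expect_equal(nrow(out$X), 49L)
  expect_equal(attr(out, "exclusions")$segment, 17L)

  # Gaussian scores: about the upper 2SD tail (~2.3%) is excluded
  set.seed(5)
  Xg <- matrix(rnorm(4000, mean = 100, sd = 1), 1000, 4)
  fmg <- make_fm(Xg, "P", rep(c("non_totonou", "totonou"), 500))
  frac <- 1 - nrow(noise_screen(fmg)$X) / 1000
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.04)

  fm_small <- make_fm(matrix(1, 2, 3), "P", c("non_totonou", "totonou"))
  expect_error(noise_screen(fm_small), class = "totonou_error_too_few_rows")
})

test_that("class balancing subsamples the majority without duplication", {
  set.seed(1)
  X <- matrix(rnorm(40 * 3), 40, 3)
  fm <- make_fm(X, "P", rep(c("totonou", "non_totonou"), c(30, 10)))
  bal <- balance_classes(fm, seed = 3)
  expect_equal(unname(table(bal$meta$class)["totonou"]), 10)
  expect_equal(unname(table(bal$meta$class)["non_totonou"]), 10)
  # subset property: every balanced row exists in the original
  expect_true(all(bal$meta$segment %in% fm$meta$segment))
  expect_false(any(duplicated(bal$meta$segment)))

  # already balanced -> unchanged
  fm2 <- make_fm(X[1:20, ], "P", rep(c("totonou", "non_totonou"), 10))
  expect_identical(balance_classes(fm2, 1)$X, fm2$X)

  fm3 <- make_fm(X[1:5, ], "P", rep("totonou", 5))
  expect_error(balance_classes(fm3, 1), class = "totonou_error_missing_class")
})

test_that("well-separated classes are decoded nearly perfectly", {
  fm <- gaussian_fm(n_per_class = 30, p = 20, delta = 5, seed = 11)
  std <- totonou:::fit_standardizer(fm$X, fm$meta$participant)
  Xs <- totonou:::apply_standardizer(std, fm$X, fm$meta$participant)
  model <- fit_decoder(Xs, fm$meta$class, seed = 1)
  expect_gte(mean(predict_decoder(model, Xs) == fm$meta$class), 0.99)
})

test_that("pure-noise features decode at chance in cross-validation", {
  fm <- gaussian_fm(n_per_class = 40, p = 20, delta = 0, seed = 21)
  std <- totonou:::fit_standardizer(fm$X, fm$meta$participant)
  Xs <- totonou:::apply_standardizer(std, fm$X, fm$meta$participant)
  model <- fit_decoder(Xs, fm$meta$class, seed = 2)
  cv_acc <- 1 - min(model$cv_error)
  expect_gt(cv_acc, 0.35)
  expect_lt(cv_acc, 0.70)
})

test_that("with all weights shrunk away prediction falls to the intercept class", {
  fm <- gaussian_fm(n_per_class = 10, p = 5, delta = 1, seed = 3)
  model <- fit_decoder(fm$X, fm$meta$class, folds = 5, seed = 1)
  model$weights[] <- 0 # the lambda -> Inf limit
  pred <- predict_decoder(model, fm$X)
  expect_equal(length(unique(pred)), 1L)

  expect_error(
    fit_decoder(fm$X, rep("totonou", 20), seed = 1),
    class = "totonou_error_single_class"
  )
})

test_that("standardization and PCA never see the test rows", {
  fm <- gaussian_fm(n_per_class = 25, p = 12, delta = 1.5, seed = 9)
  test_idx <- c(1:3, 26:28)
  ref <- totonou:::decode_split(fm, test_idx, seed = 5)

  fm_mut <- fm
  fm_mut$X[test_idx, ] <- fm_mut$X[test_idx, ] * 100 + 7 # perturb test rows only
  mut <- totonou:::decode_split(fm_mut, test_idx, seed = 5)
  expect_identical(ref$model, mut$model) # bit-identical fit
  expect_identical(ref$standardizer, mut$standardizer)
  # but predictions on the perturbed rows may differ
  expect_false(identical(ref$predicted, mut$predicted) &&
    identical(fm$X[test_idx, ], fm_mut$X[test_idx, ]))
})

test_that("evaluate_decoder reports perfect accuracy on separable participants", {
  fm <- gaussian_fm(n_per_class = 30, p = 15, delta = 6, seed = 13)
  ev <- evaluate_decoder(fm, n_splits = 5, seed = 2)
  expect_equal(ev$per_participant$accuracy_mean, 100)
  expect_equal(
    ev$pipeline[1:4],
    c("segment", "fft_power", "noise_screen", "balance")
  )
})

test_that("mean accuracy is monotone in the injected class separation", {
  accs <- sapply(c(0, 1.2, 4), function(delta) {
    mean(sapply(1:5, function(s) {
      fm <- gaussian_fm(n_per_class = 25, p = 12, delta = delta, seed = 100 + s)
      evaluate_decoder(fm, n_splits = 4, seed = s)$accuracy_mean
    }))
  })
  expect_true(all(diff(accs) >= 0))
  expect_lt(accs[1], 70)
  expect_gt(accs[3], 90)
})

test_that("label permutation keeps per-participant label counts", {
  fm <- gaussian_fm(n_per_class = 10, p = 4, delta = 2, seed = 7)
  pm <- permute_labels(fm, seed = 3)
  expect_equal(table(pm$meta$class), table(fm$meta$class))
  expect_false(identical(pm$meta$class, fm$meta$class))
})
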