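# Brain-state decoder: per-segment spectral features (4 s segments, 4-40 Hz
# at 0.5 Hz, for L, R and L-R), broadband-power noise screen, within-
# participant standardization, class balancing, PCA reduction and an
# L1-penalised linear discriminant with 10-fold cross-validated shrinkage.
# Models are fit within participant; held-out accuracy comes from stratified
# 90/10 splits. The pipeline order is fixed:
#   segment -> FFT power -> noise screen -> balance -> split ->
#   standardize(train) -> PCA(train) -> lambda-CV -> fit -> test
# with standardization and PCA parameters computed on training rows only.

decoder_classes <- function() c("non_totonou", "totonou")

stage_to_class <- function(stage) {
  ifelse(stage == "pre", "non_totonou", "totonou")
}

new_feature_matrix <- function(X, meta, grid_hz) {
  stopifnot(nrow(X) == nrow(meta))
  structure(list(X = X, meta = meta, grid_hz = grid_hz), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d segments x %d features (%d participants; %s)\n",
    nrow(x$X), ncol(x$X), length(unique(x$meta$participant)),
    paste(sprintf("%s=%d", names(table(x$meta$class)), table(x$meta$class)), collapse = ", ")
  ))
  invisible(x)
}

fm_subset <- function(fm, idx) {
  new_feature_matrix(fm$X[idx, , drop = FALSE], fm$meta[idx, , drop = FALSE], fm$grid_hz)
}

#' Build the decoder feature matrix from labelled in-ear recordings
#'
#' Each recording is band-pass filtered (default 2-45 Hz so the 30-40 Hz
#' features are informative), cut into 4 s segments, and transformed to
#' per-segment power for three signals: L, R and the time-domain difference
#' L-R. Power is binned onto a 0.5 Hz grid spanning 4-40 Hz (73 steps) by
#' summing the constituent FFT bins, giving 3 x 73 = 219 columns. Class
#' labels follow the session stage: pre maps to `non_totonou`, post1-post3
#' to `totonou`.
#'
#' @param sessions list of sessions, each a list with elements `recording`
#'   (an `eeg_recording` with channels L and R), `participant` and `stage`.
#' @param segment_s segment length in seconds (default 4).
#' @param grid_lo,grid_hi,grid_step frequency grid in Hz (defaults 4, 40,
#'   0.5).
#' @param filter_band band-pass applied before segmentation (default
#'   `c(2, 45)`); `NULL` skips filtering.
#' @return a `feature_matrix`: `X` (segments x features), `meta`
#'   (`participant`, `stage`, `class`, `segment`), `grid_hz`.
#' @export
build_features <- function(sessions, segment_s = 4,
                           grid_lo = 4, grid_hi = 40, grid_step = 0.5,
                           filter_band = c(2, 45)) {
  grid <- seq(grid_lo, grid_hi, by = grid_step)
  rows <- list()
  meta <- list()
  for (sess in sessions) {
    rec <- sess$recording
    require_channels(rec, c("L", "R"))
    if (!is.null(filter_band)) rec <- bandpass(rec, filter_band[1L], filter_band[2L])
    d <- rec$samples["L", ] - rec$samples["R", ]
    rec3 <- new_recording(
      rbind(rec$samples[c("L", "R"), , drop = FALSE], D = d),
      rec$rate_hz, c("L", "R", "D")
    )
    segs <- segment_recording(rec3, segment_s)
    spec <- power_spectrum(segs)
    f <- spec$freqs_hz
    binned <- vapply(grid, function(g) {
      inside <- f >= g - grid_step / 2 & f < g + grid_step / 2
      apply(spec$power[, , inside, drop = FALSE], c(1L, 2L), sum)
    }, matrix(0, dim(spec$power)[1L], 3L))
    # binned: segments x signals x grid -> flatten signals-major
    n_seg <- dim(spec$power)[1L]
    X <- matrix(0, n_seg, 3L * length(grid))
    for (s in 1:3) X[, ((s - 1L) * length(grid) + 1L):(s * length(grid))] <- binned[, s, ]
    colnames(X) <- as.vector(vapply(
      c("L", "R", "D"),
      function(sg) sprintf("%s_%.1f", sg, grid), character(length(grid))
    ))
    rows[[length(rows) + 1L]] <- X
    meta[[length(meta) + 1L]] <- data.frame(
      participant = sess$participant, stage = sess$stage,
      class = stage_to_class(sess$stage), segment = seq_len(n_seg),
      stringsAsFactors = FALSE
    )
  }
  new_feature_matrix(do.call(rbind, rows), do.call(rbind, meta), grid)
}

#' Screen noisy segments by broadband power
#'
#' Computes a scalar noise score per segment (total power summed over the
#' feature grid) and, within each participant, excludes segments whose score
#' exceeds the participant's mean + `k_sd` standard deviations. A zero-spread
#' participant keeps all segments.
#'
#' @param fm a `feature_matrix`.
#' @param k_sd exclusion threshold in standard deviations (default 2).
#' @return the screened `feature_matrix`; the exclusion log (participant,
#'   segment, score, threshold) is attached as attribute `"exclusions"`.
#' @export
noise_screen <- function(fm, k_sd = 2) {
  stopifnot(inherits(fm, "feature_matrix"))
  score <- rowSums(fm$X)
  keep <- rep(TRUE, length(score))
  thr <- rep(NA_real_, length(score))
  for (pid in unique(fm$meta$participant)) {
    ri <- which(fm$meta$participant == pid)
    if (length(ri) < 3L) {
      stop_totonou(sprintf("participant %s has fewer than 3 segments", pid), "too_few_rows")
    }
    s <- stats::sd(score[ri])
    t <- mean(score[ri]) + k_sd * s
    thr[ri] <- t
    if (s > 0) keep[ri] <- score[ri] <= t
  }
  out <- fm_subset(fm, which(keep))
  attr(out, "exclusions") <- data.frame(
    participant = fm$meta$participant[!keep],
    stage = fm$meta$stage[!keep], segment = fm$meta$segment[!keep],
    score = score[!keep], threshold = thr[!keep], stringsAsFactors = FALSE
  )
  out
}

#' Balance the two classes by subsampling the majority class
#'
#' Within each participant, the majority class (totonou, which pools three
#' post sets against one pre set) is subsampled without replacement to the
#' minority count. Deterministic given `seed`.
#'
#' @param fm a `feature_matrix`.
#' @param seed integer seed.
#' @return the balanced `feature_matrix` (a row subset; no duplication).
#' @export
balance_classes <- function(fm, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- with_seed(seed, {
    idx <- integer(0)
    for (pid in unique(fm$meta$participant)) {
      ri <- which(fm$meta$participant == pid)
      cls <- fm$meta$class[ri]
      counts <- table(factor(cls, levels = decoder_classes()))
      if (any(counts == 0L)) {
        stop_totonou(sprintf("participant %s lacks one class", pid), "missing_class")
      }
      n_min <- min(counts)
      for (cl in decoder_classes()) {
        rc <- ri[cls == cl]
        if (length(rc) > n_min) rc <- sort(sample(rc, n_min))
        idx <- c(idx, rc)
      }
    }
    sort(idx)
  })
  fm_subset(fm, keep)
}

#' Randomly permute class labels within participant
#'
#' Used for chance-level anchoring: with labels permuted, held-out decoding
#' accuracy must sit at 50%.
#'
#' @param fm a `feature_matrix`.
#' @param seed integer seed.
#' @return the `feature_matrix` with permuted `class` labels.
#' @export
permute_labels <- function(fm, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  with_seed(seed, {
    for (pid in unique(fm$meta$participant)) {
      ri <- which(fm$meta$participant == pid)
      fm$meta$class[ri] <- sample(fm$meta$class[ri])
    }
  })
  fm
}

# Within-participant column standardization fit on a set of rows.
fit_standardizer <- function(X, participant) {
  out <- list()
  for (pid in unique(participant)) {
    ri <- which(participant == pid)
    mu <- colMeans(X[ri, , drop = FALSE])
    sd_ <- apply(X[ri, , drop = FALSE], 2L, stats::sd)
    sd_[!is.finite(sd_) | sd_ <= 0] <- 1
    out[[pid]] <- list(mean = mu, sd = sd_)
  }
  out
}

apply_standardizer <- function(std, X, participant) {
  for (pid in unique(participant)) {
    ri <- which(participant == pid)
    if (is.null(std[[pid]])) {
      stop_totonou(sprintf("no standardization parameters for %s", pid), "missing_class")
    }
    X[ri, ] <- sweep(sweep(X[ri, , drop = FALSE], 2L, std[[pid]]$mean), 2L, std[[pid]]$sd, "/")
  }
  X
}

#' Fit the sparse linear discriminant on standardized training features
#'
#' PCA (up to `n_components`, capped at `min(features, rows - 1)`) is fit on
#' the training rows, followed by an L1-penalised linear discriminant
#' (logistic surrogate) on the PCA scores. The shrinkage parameter lambda is
#' chosen over a 50-value log-spaced grid by `folds`-fold stratified
#' cross-validation, taking the lambda with the lowest CV misclassification
#' error (ties resolved toward the larger, sparser lambda); the final
#' weights are refit on all training rows at that lambda.
#'
#' @param X numeric matrix of standardized training features.
#' @param y class labels (`non_totonou` / `totonou`).
#' @param n_components maximum number of principal components (default 150).
#' @param folds cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return a `totonou_decoder_model`: PCA centre/rotation, chosen `lambda`,
#'   discriminant `weights` and `intercept`, class levels, and the CV error
#'   curve.
#' @export
fit_decoder <- function(X, y, n_components = 150, folds = 10, seed = 1L) {
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    stop_totonou("training set contains a single class", "single_class")
  }
  counts <- table(factor(y, levels = decoder_classes()))
  if (any(counts < 2L)) stop_totonou("too few training rows per class", "too_few_rows")
  ncomp <- min(n_components, ncol(X), nrow(X) - 1L)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = ncomp)
  scores <- pca$x[, seq_len(ncomp), drop = FALSE]
  yf <- factor(y, levels = decoder_classes())
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in decoder_classes()) {
      ri <- which(y == cl)
      foldid[ri] <- sample(rep_len(seq_len(min(folds, length(ri))), length(ri)))
    }
  })
  cv <- glmnet::cv.glmnet(scores, yf,
    family = "binomial", alpha = 1,
    foldid = foldid, type.measure = "class", nlambda = 50,
    standardize = FALSE
  )
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  structure(
    list(
      pca_center = pca$center,
      pca_rotation = pca$rotation[, seq_len(ncomp), drop = FALSE],
      n_components = ncomp,
      lambda = cv$lambda.min,
      intercept = co[1L],
      weights = co[-1L],
      classes = decoder_classes(),
      cv_lambda = cv$lambda, cv_error = cv$cvm
    ),
    class = "totonou_decoder_model"
  )
}

#' @export
print.totonou_decoder_model <- function(x, ...) {
  cat(sprintf(
    "<totonou_decoder_model> %d PCA components, lambda = %.4g, %d nonzero weight(s)\n",
    x$n_components, x$lambda, sum(x$weights != 0)
  ))
  invisible(x)
}

#' Predict classes from standardized features
#'
#' @param model a `totonou_decoder_model`.
#' @param X standardized feature rows (same columns the model was fit on).
#' @return character vector of predicted classes.
#' @export
predict_decoder <- function(model, X) {
  stopifnot(inherits(model, "totonou_decoder_model"))
  scores <- sweep(X, 2L, model$pca_center) %*% model$pca_rotation
  eta <- model$intercept + as.numeric(scores %*% model$weights)
  # binomial coding: positive linear predictor -> second factor level
  ifelse(eta > 0, model$classes[2L], model$classes[1L])
}

# One stratified train/test split -> fitted model + held-out accuracy.
# Standardization and PCA are computed on training rows only and applied
# unchanged to the test rows (leakage guard).
decode_split <- function(fm, test_idx, n_components = 150, folds = 10,
                         seed = 1L, standardize = c("train", "global")) {
  standardize <- match.arg(standardize)
  train_idx <- setdiff(seq_len(nrow(fm$X)), test_idx)
  std_rows <- if (standardize == "train") train_idx else seq_len(nrow(fm$X))
  std <- fit_standardizer(fm$X[std_rows, , drop = FALSE], fm$meta$participant[std_rows])
  Xs_train <- apply_standardizer(std, fm$X[train_idx, , drop = FALSE], fm$meta$participant[train_idx])
  model <- fit_decoder(Xs_train, fm$meta$class[train_idx],
    n_components = n_components, folds = folds, seed = seed
  )
  Xs_test <- apply_standardizer(std, fm$X[test_idx, , drop = FALSE], fm$meta$participant[test_idx])
  pred <- predict_decoder(model, Xs_test)
  list(
    model = model, standardizer = std,
    accuracy = mean(pred == fm$meta$class[test_idx]),
    predicted = pred, truth = fm$meta$class[test_idx]
  )
}

stratified_test_rows <- function(class, train_fraction, seed) {
  with_seed(seed, {
    idx <- integer(0)
    for (cl in unique(class)) {
      ri <- which(class == cl)
      n_test <- max(1L, as.integer(round((1 - train_fraction) * length(ri))))
      if (n_test >= length(ri)) {
        stop_totonou("too few rows to hold out a test set", "too_few_rows")
      }
      idx <- c(idx, sample(ri, n_test))
    }
    sort(idx)
  })
}

#' Evaluate per-participant decoding accuracy
#'
#' Runs the full within-participant pipeline: noise screen, class balancing,
#' stratified 90/10 train/test splits (repeated `n_splits` times with
#' different seeds; a single-split mode is available), leakage-guarded
#' standardization and PCA on training rows, lambda selection by 10-fold CV,
#' and held-out accuracy. Group-level accuracy is tested against the 50%
#' chance level with a one-sample t-test.
#'
#' @param fm a `feature_matrix` (raw, unscreened features).
#' @param train_fraction fraction of each class used for training
#'   (default 0.9).
#' @param n_splits number of seeded splits to average over (default 20;
#'   set 1 for a single-split evaluation).
#' @param n_components,folds passed to [fit_decoder()].
#' @param seed master seed.
#' @param standardize `"train"` (fit on training rows only, default) or
#'   `"global"` (all of a participant's rows; provided for comparison).
#' @param screen_k_sd noise-screen threshold in SD (default 2).
#' @return list with `per_participant` (accuracy mean/sd, segments kept,
#'   median lambda, nonzero weights), `accuracy_mean`, `accuracy_sd`, and
#'   `t_test` (one-sample t of per-participant accuracies against 50%).
#' @export
evaluate_decoder <- function(fm, train_fraction = 0.9, n_splits = 20,
                             n_components = 150, folds = 10, seed = 1L,
                             standardize = c("train", "global"),
                             screen_k_sd = 2) {
  standardize <- match.arg(standardize)
  fm <- noise_screen(fm, k_sd = screen_k_sd)
  fm <- balance_classes(fm, seed = child_seed(seed, 1L))
  pids <- unique(fm$meta$participant)
  rows <- list()
  for (pi in seq_along(pids)) {
    pid <- pids[pi]
    sub <- fm_subset(fm, which(fm$meta$participant == pid))
    acc <- numeric(n_splits)
    lam <- numeric(n_splits)
    nnz <- numeric(n_splits)
    for (k in seq_len(n_splits)) {
      sseed <- child_seed(seed, 100L * pi + k)
      test_idx <- stratified_test_rows(sub$meta$class, train_fraction, sseed)
      res <- decode_split(sub, test_idx,
        n_components = n_components, folds = folds,
        seed = child_seed(sseed, 7L), standardize = standardize
      )
      acc[k] <- res$accuracy
      lam[k] <- res$model$lambda
      nnz[k] <- sum(res$model$weights != 0)
    }
    rows[[pi]] <- data.frame(
      participant = pid, n_segments = nrow(sub$X),
      accuracy_mean = 100 * mean(acc),
      accuracy_sd = 100 * stats::sd(acc),
      lambda_median = stats::median(lam),
      nonzero_weights_median = stats::median(nnz),
      stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, rows)
  tt <- if (nrow(per) >= 2L && stats::sd(per$accuracy_mean) > 0) {
    one_sample_t(per$accuracy_mean, mu = 50)
  } else {
    NULL
  }
  list(
    per_participant = per,
    accuracy_mean = mean(per$accuracy_mean),
    accuracy_sd = stats::sd(per$accuracy_mean),
    t_test = tt,
    pipeline = c(
      "segment", "fft_power", "noise_screen", "balance", "split",
      paste0("standardize(", standardize, ")"), "pca(train)", "lambda_cv", "fit", "test"
    )
  )
}
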