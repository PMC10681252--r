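# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny multichannel recording with deterministic content.
tiny_recording <- function(n = 4800, rate = 600, channels = c("L", "R")) {
  t <- (0:(n - 1)) / rate
  samples <- rbind(
    10 * sin(2 * pi * 10 * t),
    5 * sin(2 * pi * 6 * t + 0.3)
  )[seq_along(channels), , drop = FALSE]
  new_recording(samples, rate, channels)
}

# Build a power_spectrum object directly from a named power vector
# (frequency -> power), for argmax/tie-break tests with exact values.
make_spectrum <- function(freqs_hz, power, channels = c("L", "R"),
                          resolution_hz = 0.125) {
  pw <- array(rep(power, each = length(channels)),
    dim = c(1L, length(channels), length(freqs_hz))
  )
  structure(
    list(
      freqs_hz = freqs_hz, power = pw, resolution_hz = resolution_hz,
      channels = channels, taper = "none"
    ),
    class = "power_spectrum"
  )
}

# Build an epoch_set directly from an epoch x channel x time array.
make_epoch_set <- function(data, rate = 500, condition = "target",
                           tmin = -0.1) {
  times <- tmin + (0:(dim(data)[3] - 1)) / rate
  totonou:::new_epoch_set(data, times, paste0("ch", seq_len(dim(data)[2])),
    condition, rate,
    n_edge_dropped = 0L
  )
}

# Build a feature_matrix directly.
make_fm <- function(X, participant, class, stage = NULL) {
  if (is.null(stage)) stage <- ifelse(class == "non_totonou", "pre", "post1")
  totonou:::new_feature_matrix(
    X,
    data.frame(
      participant = participant, stage = stage, class = class,
      segment = seq_len(nrow(X)), stringsAsFactors = FALSE
    ),
    grid_hz = seq_len(ncol(X))
  )
}

# Gaussian two-class feature matrix with a given mean separation (in SD).
gaussian_fm <- function(n_per_class = 30, p = 20, delta = 0, seed = 1,
                        participant = "S1") {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_per_class * p), n_per_class, p),
    matrix(stats::rnorm(n_per_class * p, mean = delta), n_per_class, p)
  )
  make_fm(X, participant,
    class = rep(c("non_totonou", "totonou"), each = n_per_class)
  )
}

# Exhaustive validator for oddball sequences: counts and the gap constraint.
validate_sequence <- function(sq, n_total, n_targets, min_gap) {
  if (length(sq) != n_total) return(FALSE)
  if (sum(sq == "target") != n_targets) return(FALSE)
  pos <- which(sq == "target")
  if (length(pos) >= 2L && any(diff(pos) - 1L < min_gap)) return(FALSE)
  all(sq %in% c("standard", "target"))
}

# Balanced mixed-design data frame generator for ANOVA tests.
null_anova_data <- function(n_per_group = 10, levels = 4) {
  data.frame(
    participant = rep(sprintf("S%02d", 1:(2 * n_per_group)), each = levels),
    group = rep(c("a", "b"), each = n_per_group * levels),
    level = rep(paste0("l", seq_len(levels)), times = 2 * n_per_group),
    value = stats::rnorm(2 * n_per_group * levels)
  )
}

# Brute-force sums-of-squares oracle for the balanced two-way mixed design,
# written from the definitional cell/marginal means (independent of aov).
mixed_anova_oracle <- function(d) {
  d$participant <- as.character(d$participant)
  d$group <- as.character(d$group)
  d$level <- as.character(d$level)
  groups <- sort(unique(d$group))
  levels_ <- sort(unique(d$level))
  subs <- unique(d[, c("participant", "group")])
  n <- nrow(subs) / length(groups)
  a <- length(groups); b <- length(levels_)
  grand <- mean(d$value)
  m_group <- tapply(d$value, d$group, mean)
  m_level <- tapply(d$value, d$level, mean)
  m_cell <- tapply(d$value, list(d$group, d$level), mean)
  m_subj <- tapply(d$value, d$participant, mean)
  ss_group <- n * b * sum((m_group - grand)^2)
  ss_between_subj <- b * sum((m_subj - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_level <- a * n * sum((m_level - grand)^2)
  dev <- sweep(sweep(m_cell, 1L, m_group), 2L, m_level) + grand
  ss_int <- n * sum(dev^2)
  ss_total <- sum((d$value - grand)^2)
  ss_err_w <- ss_total - ss_between_subj - ss_level - ss_int
  df_g <- a - 1; df_sw <- a * (n - 1)
  df_l <- b - 1; df_i <- (a - 1) * (b - 1); df_ew <- a * (n - 1) * (b - 1)
  f <- function(ss, df, ss_e, df_e) (ss / df) / (ss_e / df_e)
  list(
    group = c(F = f(ss_group, df_g, ss_subj_within, df_sw), df1 = df_g, df2 = df_sw),
    level = c(F = f(ss_level, df_l, ss_err_w, df_ew), df1 = df_l, df2 = df_ew),
    interaction = c(F = f(ss_int, df_i, ss_err_w, df_ew), df1 = df_i, df2 = df_ew),
    ms_error_within = ss_err_w / df_ew
  )
}
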