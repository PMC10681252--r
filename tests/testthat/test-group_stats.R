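# Mixed-design ANOVA, simple main effects, Holm pairwise comparisons,
# correlations and one-sample t.

test_that("mixed_anova matches the brute-force sums-of-squares oracle", {
  set.seed(42)
  for (n in c(2, 3)) {
    for (b in c(2, 3, 4)) {
      for (rep_ in 1:3) {
        d <- data.frame(
          participant = rep(sprintf("S%d", 1:(2 * n)), each = b),
          group = rep(c("a", "b"), each = n * b),
          level = rep(paste0("l", 1:b), times = 2 * n),
          value = sample(0:9, 2 * n * b, replace = TRUE) + rnorm(2 * n * b, 0, 0.01)
        )
        got <- mixed_anova(d)
        want <- mixed_anova_oracle(d)
        for (eff in c("group", "level", "interaction")) {
          expect_equal(got[[eff]][["F"]], want[[eff]][["F"]], tolerance = 1e-8)
          expect_equal(got[[eff]][["df"]], unname(want[[eff]][["df1"]]))
        }
        expect_equal(got$ms_error_within, want$ms_error_within, tolerance = 1e-8)
        expect_equal(got$df_error_within, unname(want$interaction[["df2"]]))
      }
    }
  }
})

test_that("degenerate inputs are handled: constants, missing cells, tiny n", {
  d <- null_anova_data(3, 4)
  d$value <- 5
  res <- mixed_anova(d)
  expect_equal(res$group[["F"]], 0)
  expect_equal(res$level[["F"]], 0)
  expect_equal(res$interaction[["F"]], 0)

  expect_error(mixed_anova(d[-1, ]), class = "totonou_error_missing_cells")

  d1 <- null_anova_data(1, 4)
  expect_error(mixed_anova(d1), class = "totonou_error_insufficient_replication")

  d2 <- null_anova_data(3, 4)
  d2 <- d2[d2$level == "l1", ]
  expect_error(mixed_anova(d2), class = "totonou_error_nothing_to_test")
})

test_that("a pure crossed interaction loads only the interaction term", {
  # group a: (1, -1), group b: (-1, 1) across two levels; tiny subject noise
  set.seed(1)
  n <- 4
  d <- expand.grid(
    participant = sprintf("S%d", 1:(2 * n)), level = c("l1", "l2"),
    stringsAsFactors = FALSE
  )
  d$group <- ifelse(as.integer(sub("S", "", d$participant)) <= n, "a", "b")
  d$value <- ifelse(d$group == "a", 1, -1) * ifelse(d$level == "l1", 1, -1) +
    rnorm(nrow(d), 0, 1e-6)
  res <- mixed_anova(d)
  expect_lt(res$interaction[["p"]], 1e-10)
  # main effects stay at the numerical-noise scale
  expect_gt(res$interaction[["F"]], 1e6 * max(res$group[["F"]], res$level[["F"]]))
})

test_that("simple main effects isolate the group carrying the set effect", {
  set.seed(33)
  hits_a <- 0; hits_b <- 0
  for (k in 1:20) {
    d <- null_anova_data(8, 4)
    bump <- (as.integer(factor(d$level)) - 1) * 2.0
    d$value <- d$value + ifelse(d$group == "a", bump, 0)
    sme <- simple_main_effects(mixed_anova(d))
    hits_a <- hits_a + sme$significant[sme$group == "a"]
    hits_b <- hits_b + sme$significant[sme$group == "b"]
  }
  expect_gte(hits_a, 19)
  expect_lte(hits_b, 3)

  # flat identical groups: neither simple effect is significant
  d0 <- null_anova_data(6, 3)
  d0$value <- 2
  sme0 <- simple_main_effects(mixed_anova(d0))
  expect_false(any(sme0$significant))
})

test_that("holm_pairwise reproduces the step-down adjustment", {
  means <- c(pre = 10, post1 = 14, post2 = 15, post3 = 15.5)
  pw <- holm_pairwise(means, ms_error = 4, n = 10, df_error = 54)
  expect_equal(nrow(pw), 6L)
  # oracle: hand-rolled step-down on the raw p values
  ord <- order(pw$p_raw)
  m <- length(ord)
  adj <- numeric(m)
  prev <- 0
  for (i in seq_len(m)) {
    adj[ord[i]] <- max(prev, min(1, (m - i + 1) * pw$p_raw[ord[i]]))
    prev <- adj[ord[i]]
  }
  expect_equal(pw$p_holm, adj, tolerance = 1e-12)
  # monotone and never below raw
  expect_true(all(pw$p_holm >= pw$p_raw - 1e-15))
  expect_true(all(diff(pw$p_holm[ord]) >= -1e-15))

  # a single comparison is unadjusted
  pw1 <- holm_pairwise(c(a = 1, b = 3), ms_error = 4, n = 10, df_error = 18)
  expect_equal(pw1$p_holm, pw1$p_raw)

  # identical means: nothing significant
  pw0 <- holm_pairwise(c(a = 2, b = 2, c = 2), ms_error = 1, n = 5, df_error = 24)
  expect_false(any(pw0$significant))
})

test_that("pearson_change_correlation recovers exact linear relations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_change_correlation(x, 2 * x)$r, 1)
  expect_equal(pearson_change_correlation(x, -x + 10)$r, -1)
  out <- pearson_change_correlation(x, c(2, 1, 4, 3, 6))
  expect_equal(out$df, 3)
  expect_error(
    pearson_change_correlation(x, rep(1, 5)),
    class = "totonou_error_zero_variance"
  )
  expect_error(
    pearson_change_correlation(1:2, 2:1),
    class = "totonou_error_insufficient_replication"
  )
})

test_that("one_sample_t matches the closed form", {
  v <- c(60, 60, 60, 80, 80, 80, 70, 70, 70, 70)
  out <- one_sample_t(v, 50)
  expect_equal(out$df, 9)
  expect_equal(out$t, (mean(v) - 50) / (sd(v) / sqrt(10)), tolerance = 1e-12)

  expect_equal(one_sample_t(c(49, 51, 50.5, 49.5), 50)$t, 0)
  expect_error(one_sample_t(rep(3, 4), 3), class = "totonou_error_zero_variance")
  expect_error(one_sample_t(5, 3), class = "totonou_error_insufficient_replication")
})

test_that("score coupling in simulated cohorts is recovered by correlation", {
  rs <- sapply(1:4, function(k) {
    co <- simulate_cohort(
      cohort_design(seed = 500 + k, rest_duration_s = 16, score_coupling = 0.8),
      modalities = c("inear", "scores")
    )
    bp <- cohort_band_powers(co)
    cc <- score_change_correlation(bp, co$scores, band = "theta", items = c("Q2", "Q4", "Q14"))
    mean(cc$r)
  })
  expect_gt(mean(rs), 0.5)
  expect_lt(mean(rs), 0.98)
})
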