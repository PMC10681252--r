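# Two-way mixed-design ANOVA (between: group; within: set/stage), simple
# main effects against the pooled within-subject error, Holm-Bonferroni
# pairwise comparisons, Pearson change correlations and one-sample t-tests.

#' Two-way mixed-design ANOVA
#'
#' One between-subjects factor (`group`) crossed with one within-subjects
#' factor (`level`, the sauna set or stage). Fit via `stats::aov` with an
#' `Error(participant)` stratum, so the group effect is tested against the
#' between-subject error and the within effect and interaction against the
#' subject-by-level error. The design must be complete and balanced (every
#' participant measured at every level, equal group sizes); missing cells are
#' an error, never imputed.
#'
#' @param data a `data.frame` with columns `participant`, `group`, `level`,
#'   `value` (further columns are ignored).
#' @return a `mixed_anova_result`: per-effect F, df and p, the within error
#'   mean square `ms_error_within` with its df, cell means, and the data
#'   (for simple main effects).
#' @export
mixed_anova <- function(data) {
  need <- c("participant", "group", "level", "value")
  if (!all(need %in% names(data))) {
    stop_totonou("data needs columns participant, group, level, value", "bad_parameter")
  }
  d <- data.frame(
    participant = factor(data$participant),
    group = factor(data$group),
    level = factor(data$level),
    value = as.numeric(data$value)
  )
  if (anyNA(d$value)) stop_totonou("missing values in design cells", "missing_cells")
  tab <- table(d$participant, d$level)
  if (any(tab != 1L)) {
    stop_totonou("design incomplete: every participant needs one value per level", "missing_cells")
  }
  pg <- unique(d[, c("participant", "group")])
  n_per_group <- table(pg$group)
  if (length(unique(n_per_group)) != 1L) {
    stop_totonou("unbalanced groups: equal group sizes required", "missing_cells")
  }
  if (min(n_per_group) < 2L) {
    stop_totonou("insufficient replication: need >= 2 participants per group", "insufficient_replication")
  }
  if (nlevels(d$level) < 2L) {
    stop_totonou("nothing to test: a single within level", "nothing_to_test")
  }
  fit <- stats::aov(value ~ group * level + Error(participant), data = d)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: participant"]][[1L]])
  wth <- as.data.frame(sm[["Error: Within"]][[1L]])
  rn_b <- trimws(rownames(btw))
  rn_w <- trimws(rownames(wth))
  # sums of squares at numerical-noise scale count as exactly zero, so that
  # constant data reports F = 0 rather than a 0/0 or noise/noise ratio
  ss_tol <- 1e-10 * (1 + sum(d$value^2))
  pick <- function(tb, rn, name) {
    i <- match(name, rn)
    out <- c(df = tb[i, "Df"], ss = tb[i, "Sum Sq"], ms = tb[i, "Mean Sq"],
      F = tb[i, "F value"], p = tb[i, "Pr(>F)"])
    if (!is.na(out[["ss"]]) &&
        (out[["ss"]] < ss_tol) &&
        (is.na(out[["F"]]) || is.nan(out[["F"]]) || tb[match("Residuals", rn), "Sum Sq"] < ss_tol)) {
      out[["F"]] <- 0
      out[["p"]] <- 1
    }
    out
  }
  grp <- pick(btw, rn_b, "group")
  lvl <- pick(wth, rn_w, "level")
  ixn <- pick(wth, rn_w, "group:level")
  err_b <- btw[match("Residuals", rn_b), ]
  err_w <- wth[match("Residuals", rn_w), ]
  cell_means <- tapply(d$value, list(d$group, d$level), mean)
  structure(
    list(
      group = grp, level = lvl, interaction = ixn,
      ms_error_between = err_b[["Mean Sq"]], df_error_between = err_b[["Df"]],
      ms_error_within = err_w[["Mean Sq"]], df_error_within = err_w[["Df"]],
      cell_means = cell_means,
      n_per_group = as.integer(n_per_group[1L]),
      groups = levels(d$group), levels = levels(d$level),
      data = d
    ),
    class = "mixed_anova_result"
  )
}

fmt_effect <- function(name, e) {
  sprintf(
    "  %-12s F(%d, %d) = %.2f, p = %.4g%s", name,
    e[["df"]], attr(e, "df2"), e[["F"]], e[["p"]],
    if (e[["p"]] < 0.05) " *" else if (e[["p"]] < 0.1) " +" else ""
  )
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat("<mixed_anova_result>\n")
  for (nm in c("group", "level", "interaction")) {
    e <- x[[nm]]
    df2 <- if (nm == "group") x$df_error_between else x$df_error_within
    attr(e, "df2") <- df2
    cat(fmt_effect(nm, e), "\n")
  }
  cat(sprintf("  within error MS = %.4f (df = %d)\n", x$ms_error_within, x$df_error_within))
  invisible(x)
}

#' Simple main effects of the within factor, per group
#'
#' Decomposes a significant group-by-level interaction: the within-factor
#' effect is tested separately inside each group, against the pooled
#' within-subject error term of the full model (so the error df match the
#' omnibus test, e.g. F(3, 54) for 2 groups of 10 over 4 sets).
#'
#' @param result a `mixed_anova_result`.
#' @return a `data.frame` with one row per group: F, df1, df2, p and
#'   significance flags (`significant` at 0.05, `marginal` at 0.1).
#' @export
simple_main_effects <- function(result) {
  stopifnot(inherits(result, "mixed_anova_result"))
  d <- result$data
  b <- nlevels(d$level)
  if (b < 2L) stop_totonou("nothing to test: a single within level", "nothing_to_test")
  n <- result$n_per_group
  rows <- lapply(result$groups, function(g) {
    dg <- d[d$group == g, ]
    lm_ <- tapply(dg$value, dg$level, mean)
    ss <- n * sum((lm_ - mean(lm_))^2)
    ms <- ss / (b - 1)
    f <- ms / result$ms_error_within
    if (ss < 1e-12 && !is.finite(f)) f <- 0 # flat cell means in a noiseless design
    p <- stats::pf(f, b - 1, result$df_error_within, lower.tail = FALSE)
    data.frame(
      group = g, F = f, df1 = b - 1, df2 = result$df_error_within, p = p,
      significant = p < 0.05, marginal = p < 0.1, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Holm-Bonferroni pairwise comparisons of within-factor levels
#'
#' All pairwise t comparisons of level means using the pooled within-subject
#' error mean square, with Holm's step-down adjustment. This is the post-hoc
#' test applied after a significant simple main effect of set.
#'
#' @param level_means named numeric vector of level means (one group).
#' @param ms_error pooled within-subject error mean square from
#'   [mixed_anova()].
#' @param n number of participants contributing to each level mean.
#' @param df_error error df of `ms_error`.
#' @param alpha family-wise significance level (default 0.05).
#' @return a `data.frame` with one row per pair: difference, t, raw and
#'   Holm-adjusted p, and flags at `alpha` (plus a marginal flag at 0.1).
#' @export
holm_pairwise <- function(level_means, ms_error, n, df_error, alpha = 0.05) {
  if (length(level_means) < 2L) stop_totonou("need >= 2 levels", "nothing_to_test")
  nm <- names(level_means)
  if (is.null(nm)) nm <- paste0("L", seq_along(level_means))
  pairs <- utils::combn(seq_along(level_means), 2L)
  se <- sqrt(2 * ms_error / n)
  out <- data.frame(
    level_a = nm[pairs[1L, ]], level_b = nm[pairs[2L, ]],
    difference = level_means[pairs[2L, ]] - level_means[pairs[1L, ]],
    stringsAsFactors = FALSE
  )
  out$t <- out$difference / se
  out$p_raw <- 2 * stats::pt(-abs(out$t), df_error)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out$significant <- out$p_holm < alpha
  out$marginal <- out$p_holm < 0.1
  rownames(out) <- NULL
  out
}

#' Pearson correlation between neural change and score change
#'
#' Product-moment correlation of paired post3-minus-pre deltas (e.g. theta
#' power change vs a questionnaire item change) with the two-sided t-based
#' p-value.
#'
#' @param neural_delta numeric vector of neural changes, one per participant.
#' @param score_delta numeric vector of score changes, same participants in
#'   the same order.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
pearson_change_correlation <- function(neural_delta, score_delta) {
  if (length(neural_delta) != length(score_delta)) {
    stop_totonou("paired vectors required", "bad_parameter")
  }
  ok <- stats::complete.cases(neural_delta, score_delta)
  x <- neural_delta[ok]
  y <- score_delta[ok]
  if (length(x) < 3L) stop_totonou("need n >= 3 pairs", "insufficient_replication")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_totonou("zero variance in one of the vectors", "zero_variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = unname(ct$parameter), n = length(x))
}

#' One-sample t-test
#'
#' Tests whether the mean of `values` differs from `mu` (used to compare
#' per-participant decoding accuracies against the 50% chance level).
#'
#' @param values numeric vector, n >= 2 with nonzero variance.
#' @param mu null-hypothesis mean.
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
one_sample_t <- function(values, mu) {
  if (length(values) < 2L) stop_totonou("need n >= 2", "insufficient_replication")
  if (stats::sd(values) == 0) stop_totonou("zero variance", "zero_variance")
  tt <- stats::t.test(values, mu = mu)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean = unname(tt$estimate)
  )
}
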