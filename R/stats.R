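#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way fixed-effects ANOVA from per-group
#' `(n, mean, sd)` triples, as needed when only published summary tables are
#' available. With group sizes \eqn{n_i}, means \eqn{m_i} and sample
#' standard deviations \eqn{s_i} (the \eqn{n-1} convention):
#' \deqn{SS_B = \sum_i n_i (m_i - \bar m)^2, \quad
#'       SS_W = \sum_i (n_i - 1) s_i^2,}
#' with \eqn{\bar m} the size-weighted grand mean, and
#' \eqn{F = [SS_B/(k-1)] / [SS_W/(N-k)]}. This is algebraically identical to
#' the classic raw-data decomposition, so the two entry points agree to
#' machine precision.
#'
#' @param groups A data frame with columns `n`, `mean`, `sd` and optionally
#'   `label`; one row per group, each `n >= 2`.
#' @return An object of class `fwhm_anova` (fields `f_statistic`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`, `p_value`, ...).
#'   Degenerate inputs: all SDs zero with equal means gives `F = 0`; all SDs
#'   zero with unequal means gives `F = Inf`, `p = 0`.
#' @examples
#' anova_from_summary(tibble::tibble(
#'   label = c("IHD", "MA", "control"),
#'   n = c(91, 29, 66),
#'   mean = c(112.482, 114.503, 118.845),
#'   sd = c(14.686, 15.470, 12.498)
#' ))
#' @export
anova_from_summary <- function(groups) {
  if (!is.data.frame(groups) || !all(c("n", "mean", "sd") %in% names(groups))) {
    stop_octfwhm("`groups` must have columns n, mean, sd.", "validation")
  }
  n <- groups$n
  m <- groups$mean
  s <- groups$sd
  if (nrow(groups) < 2L) {
    stop_octfwhm("At least two groups are required.", "validation")
  }
  if (any(n < 2) || any(s < 0) || anyNA(c(n, m, s))) {
    stop_octfwhm("Each group needs n >= 2, sd >= 0, no missing values.",
                 "validation")
  }
  k <- length(n)
  N <- sum(n)
  grand <- sum(n * m) / N
  ss_b <- sum(n * (m - grand)^2)
  ss_w <- sum((n - 1) * s^2)
  df_b <- k - 1L
  df_w <- N - k
  if (ss_w == 0) {
    f <- if (ss_b == 0) 0 else Inf
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df_b, df_w, lower.tail = FALSE)
  structure(
    list(f_statistic = f, df_between = as.integer(df_b),
         df_within = as.integer(df_w), ss_between = ss_b, ss_within = ss_w,
         p_value = p, grand_mean = grand, n_total = as.integer(N),
         groups = as_tibble(groups), source = "summary"),
    class = "fwhm_anova"
  )
}

#' One-way ANOVA from raw observations
#'
#' Classic between/within decomposition computed directly from the data;
#' agrees with [anova_from_summary()] applied to the per-group summaries to
#' machine precision.
#'
#' @param data A data frame of observations.
#' @param value,group Columns holding the response and the group label
#'   (tidy-eval).
#' @return An `fwhm_anova` object (see [anova_from_summary()]).
#' @examples
#' df <- tibble::tibble(g = rep(c("a", "b"), each = 5), y = rnorm(10))
#' anova_raw(df, y, g)
#' @export
anova_raw <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  anova_raw_vec(v, g)
}

# Vector work-horse shared by anova_raw() and the null-calibration loop.
anova_raw_vec <- function(v, g) {
  if (anyNA(v) || anyNA(g)) {
    stop_octfwhm("Missing values are not allowed.", "validation")
  }
  g <- as.factor(g)
  cnt <- tabulate(g)
  if (nlevels(g) < 2L) {
    stop_octfwhm("At least two groups are required.", "validation")
  }
  if (any(cnt < 2L)) {
    stop_octfwhm("Each group needs at least two observations.", "input")
  }
  means <- vapply(split(v, g), mean, numeric(1))
  grand <- mean(v)
  ss_b <- sum(cnt * (means - grand)^2)
  ss_w <- sum((v - means[as.integer(g)])^2)
  k <- nlevels(g)
  N <- length(v)
  df_b <- k - 1L
  df_w <- N - k
  if (ss_w <= .Machine$double.eps * sum(v^2)) {
    ss_w <- 0
    f <- if (ss_b <= .Machine$double.eps * max(1, sum(v^2))) 0 else Inf
  } else {
    f <- (ss_b / df_b) / (ss_w / df_w)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df_b, df_w, lower.tail = FALSE)
  sds <- vapply(split(v, g), sd, numeric(1))
  structure(
    list(f_statistic = f, df_between = as.integer(df_b),
         df_within = as.integer(df_w), ss_between = ss_b, ss_within = ss_w,
         p_value = p, grand_mean = grand, n_total = as.integer(N),
         groups = tibble(label = levels(g), n = cnt, mean = means, sd = sds),
         source = "raw"),
    class = "fwhm_anova"
  )
}

#' @export
print.fwhm_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s data): F(%d, %d) = %.4g, p = %.4g\n",
              x$source, x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' @rdname anova_from_summary
#' @param x An `fwhm_anova` object.
#' @param ... Unused.
#' @export
tidy.fwhm_anova <- function(x, ...) {
  tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$ss_within / x$df_within),
    statistic = c(x$f_statistic, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' @rdname anova_from_summary
#' @export
glance.fwhm_anova <- function(x, ...) {
  tibble(statistic = x$f_statistic, p.value = x$p_value,
         df = x$df_between, df.residual = x$df_within, nobs = x$n_total)
}

#' Fisher's LSD pairwise comparisons
#'
#' Unadjusted pairwise t-tests using the ANOVA's pooled within-group
#' variance: for groups i, j,
#' \deqn{t = (m_i - m_j) / \sqrt{MSE (1/n_i + 1/n_j)}}
#' with two-sided p from the t distribution on the within-group degrees of
#' freedom. LSD applies no multiplicity adjustment by definition.
#'
#' @inheritParams anova_from_summary
#' @param mse Pooled within-group mean square; taken from
#'   [anova_from_summary()] on `groups` when omitted.
#' @param df Within-group degrees of freedom; likewise derived when omitted.
#' @return A tibble with one row per pair: `group1`, `group2`, `difference`,
#'   `std_error`, `statistic`, `p_value`.
#' @export
lsd_pairwise <- function(groups, mse = NULL, df = NULL) {
  if (is.null(mse) || is.null(df)) {
    fit <- anova_from_summary(groups)
    if (is.null(mse)) mse <- fit$ss_within / fit$df_within
    if (is.null(df)) df <- fit$df_within
  }
  check_number(mse, "mse", positive = TRUE)
  check_number(df, "df", positive = TRUE)
  lab <- if ("label" %in% names(groups)) as.character(groups$label)
         else paste0("group", seq_len(nrow(groups)))
  pairs <- utils::combn(nrow(groups), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1L, c_]
    j <- pairs[2L, c_]
    diff <- groups$mean[i] - groups$mean[j]
    se <- sqrt(mse * (1 / groups$n[i] + 1 / groups$n[j]))
    t <- diff / se
    tibble(group1 = lab[i], group2 = lab[j], difference = diff,
           std_error = se, statistic = t,
           p_value = 2 * pt(-abs(t), df))
  })
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}. Suited to the ordinal severity
#' grades this package correlates with vessel calibers.
#'
#' @param x A numeric/ordinal vector, or a data frame (then `y` and `...`
#'   name its columns, tidy-eval).
#' @param y A numeric vector of the same length (vector interface), or the
#'   second column (data-frame interface).
#' @param ... Passed between methods.
#' @return An object of class `fwhm_cor` with fields `rho`, `p_value`, `n`,
#'   `statistic` (the t value), `df`.
#' @examples
#' spearman_rank(c(1, 2, 3, 4, 5), c(2.3, 2.1, 3.9, 4.4, 7.0))
#' @export
spearman_rank <- function(x, y, ...) UseMethod("spearman_rank")

#' @rdname spearman_rank
#' @export
spearman_rank.data.frame <- function(x, y, ...) {
  vars <- rlang::enquos(y, ...)
  if (length(vars) != 2L) {
    stop_octfwhm("Data-frame interface needs exactly two column names.",
                 "validation")
  }
  spearman_rank.default(rlang::eval_tidy(vars[[1L]], x),
                        rlang::eval_tidy(vars[[2L]], x))
}

#' @rdname spearman_rank
#' @export
spearman_rank.default <- function(x, y, ...) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop_octfwhm("`x` and `y` must have equal length.", "validation")
  }
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    stop_octfwhm("At least three complete pairs are required.", "validation")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) {
    stop_octfwhm("Rank variance is zero; correlation undefined.",
                 "degenerate")
  }
  rho <- sum(dx * dy) / den
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    t <- sign(rho) * Inf
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t), n - 2)
  }
  structure(list(rho = rho, p_value = p, n = as.integer(n), statistic = t,
                 df = as.integer(n - 2L)),
            class = "fwhm_cor")
}

#' @export
print.fwhm_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.4g, p = %.4g (n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' @rdname spearman_rank
#' @export
tidy.fwhm_cor <- function(x, ...) {
  tibble(estimate = x$rho, statistic = x$statistic, p.value = x$p_value,
         parameter = x$df, nobs = x$n, method = "spearman (t approximation)")
}

#' Chi-square / Fisher test on a contingency table
#'
#' Pearson chi-square statistic \eqn{\sum (O - E)^2 / E} (no continuity
#' correction) on an r-by-k table of counts; when any expected cell count
#' falls below 5, the method switches to Fisher's exact test, and the choice
#' is recorded in the output.
#'
#' @param counts A matrix (or data frame of counts coercible to one) of
#'   non-negative integers; rows are outcome levels, columns are groups.
#' @return A one-row tibble: `statistic` (chi-square; `NA` for the exact
#'   test), `df`, `p_value`, `method`, `min_expected`.
#' @examples
#' categorical_test(matrix(c(30, 61, 14, 15, 30, 36), nrow = 2))
#' @export
categorical_test <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_octfwhm("`counts` must be non-negative integers.", "validation")
  }
  if (is.null(dim(counts)) || any(dim(counts) < 2L)) {
    stop_octfwhm("`counts` must be at least a 2 x 2 table.", "validation")
  }
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop_octfwhm("Contingency table has an empty margin.", "validation")
  }
  expected <- outer(rs, cs) / sum(counts)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  if (any(expected < 5)) {
    p <- fisher.test(counts)$p.value
    tibble(statistic = NA_real_, df = NA_integer_, p_value = p,
           method = "fisher", min_expected = min(expected))
  } else {
    x2 <- sum((counts - expected)^2 / expected)
    tibble(statistic = x2, df = df,
           p_value = pchisq(x2, df, lower.tail = FALSE),
           method = "chi-square", min_expected = min(expected))
  }
}

#' Per-group Shapiro-Wilk normality screen
#'
#' Reported alongside the ANOVA as a descriptive screen; it never gates the
#' analysis.
#'
#' @inheritParams anova_raw
#' @return A tibble with one row per group: `label`, `n`, `w`, `p_value`.
#' @export
normality_screen <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  purrr::map_dfr(levels(g), function(l) {
    vi <- v[g == l]
    sw <- shapiro.test(vi)
    tibble(label = l, n = length(vi), w = unname(sw$statistic),
           p_value = sw$p.value)
  })
}
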