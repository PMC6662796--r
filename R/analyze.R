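vessel_param_cols <- c(RALD = "rald_um", RAOD = "raod_um", RVLD = "rvld_um",
                       RVOD = "rvod_um", AVR = "avr", AWT = "awt_um",
                       VWT = "vwt_um")
table2_order <- c("RALD", "RAOD", "RVLD", "RVOD", "AVR", "AWT", "VWT")
group_order <- c("IHD", "MA", "control")

#' Summarize vessel parameters per group
#'
#' Collapses a subject table to per-parameter, per-group `(n, mean, sd)`
#' rows — the summary form that [anova_from_summary()] consumes, and the
#' format of the packaged reference summaries.
#'
#' @param subjects A subject tibble (see [subject_record()]).
#' @return A tibble with columns `parameter`, `group`, `n`, `mean`, `sd`.
#' @export
group_vessel_summaries <- function(subjects) {
  purrr::map_dfr(names(vessel_param_cols), function(p) {
    subjects |>
      dplyr::group_by(group = .data$group) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data[[vessel_param_cols[[p]]]]),
        sd = sd(.data[[vessel_param_cols[[p]]]]),
        .groups = "drop"
      ) |>
      dplyr::mutate(parameter = p, .before = 1L)
  }) |>
    dplyr::arrange(match(.data$parameter, table2_order),
                   match(.data$group, group_order))
}

#' Full cohort analysis
#'
#' Runs the study's statistical battery on a subject table and returns the
#' three result tables:
#' * `table1` — covariate comparability across groups: one-way ANOVA for
#'   numeric covariates (age, BMI), chi-square (or Fisher's exact, when an
#'   expected count falls below 5) for binary ones;
#' * `table2` — per-parameter group means +/- SD with the one-way ANOVA F
#'   and p, plus Fisher's LSD pairwise p-values nested in `lsd`;
#' * `table3` — Spearman rank correlation of each vessel parameter with the
#'   supplied ordinal severity grade.
#'
#' @param subjects A subject tibble (see [subject_record()], [make_cohort()]).
#' @param severity_subset Optional filter for the correlation analysis
#'   (e.g. patient groups only); default uses every subject with a
#'   non-missing severity grade.
#' @return A list of tibbles `table1`, `table2`, `table3`.
#' @examples
#' res <- analyze_cohort(make_cohort(synth_cohort_spec(seed = 3)))
#' res$table2
#' @export
analyze_cohort <- function(subjects, severity_subset = NULL) {
  if (!is.data.frame(subjects) || nrow(subjects) == 0L) {
    stop_octfwhm("`subjects` must contain at least one record.", "validation")
  }
  subjects <- dplyr::mutate(
    subjects, group = factor(.data$group, levels = group_order))
  if (anyNA(subjects$group)) {
    stop_octfwhm("Unknown group label in `subjects`.", "validation")
  }

  table1 <- covariate_table(subjects)

  table2 <- purrr::map_dfr(table2_order, function(p) {
    col <- vessel_param_cols[[p]]
    fit <- anova_raw_vec(subjects[[col]], subjects$group)
    wide <- fit$groups |>
      dplyr::mutate(cell = sprintf("%.3f ± %.3f", .data$mean, .data$sd)) |>
      dplyr::select("label", "cell") |>
      tidyr::pivot_wider(names_from = "label", values_from = "cell")
    lsd <- lsd_pairwise(fit$groups,
                        mse = fit$ss_within / fit$df_within,
                        df = fit$df_within)
    dplyr::bind_cols(
      tibble(parameter = p), wide,
      tibble(f_statistic = fit$f_statistic, p_value = fit$p_value,
             lsd = list(lsd))
    )
  })

  if (is.null(severity_subset)) {
    sev <- dplyr::filter(subjects, !is.na(.data$severity_grade))
  } else {
    sev <- dplyr::filter(subjects, .data$group %in% severity_subset,
                         !is.na(.data$severity_grade))
  }
  table3 <- purrr::map_dfr(table2_order, function(p) {
    ct <- spearman_rank(sev$severity_grade, sev[[vessel_param_cols[[p]]]])
    tibble(parameter = p, rho = ct$rho, p_value = ct$p_value, n = ct$n)
  })

  list(table1 = table1, table2 = table2, table3 = table3)
}

covariate_table <- function(subjects) {
  numeric_row <- function(var, label) {
    fit <- anova_raw_vec(subjects[[var]], subjects$group)
    wide <- fit$groups |>
      dplyr::mutate(cell = sprintf("%.2f ± %.2f", .data$mean, .data$sd)) |>
      dplyr::select("label", "cell") |>
      tidyr::pivot_wider(names_from = "label", values_from = "cell")
    dplyr::bind_cols(tibble(variable = label, type = "numeric"), wide,
                     tibble(statistic = fit$f_statistic,
                            p_value = fit$p_value, method = "anova"))
  }
  binary_row <- function(flag, label) {
    counts <- table(factor(flag, levels = c(TRUE, FALSE)), subjects$group)
    res <- categorical_test(unclass(counts))
    pos <- counts[1L, ]
    tot <- colSums(counts)
    cells <- sprintf("%d (%.1f%%)", pos, 100 * pos / tot)
    wide <- tibble::as_tibble(setNames(as.list(cells), colnames(counts)))
    dplyr::bind_cols(tibble(variable = label, type = "binary"), wide,
                     tibble(statistic = res$statistic, p_value = res$p_value,
                            method = res$method))
  }
  dplyr::bind_rows(
    numeric_row("age", "age"),
    binary_row(subjects$sex == "male", "male_sex"),
    binary_row(subjects$diabetes, "diabetes"),
    binary_row(subjects$smoker, "smoker"),
    binary_row(subjects$hypertension, "hypertension"),
    binary_row(subjects$dyslipidemia, "dyslipidemia"),
    numeric_row("bmi", "bmi")
  )
}

#' Reproduce the published group comparison from packaged summaries
#'
#' Recomputes the per-parameter one-way ANOVA F and p directly from the
#' packaged `(n, mean, SD)` group summaries, and the wall thicknesses
#' implied by the printed diameter means through the identity
#' `wall = (outer - lumen) / 2`.
#'
#' @param summaries Summary tibble in the [vessel_group_summaries()] format.
#' @return A list with `anova` (tibble: `parameter`, `f_statistic`,
#'   `p_value`) and `wall_identity` (tibble: `group`, `awt_um`, `vwt_um`
#'   derived from the diameter means).
#' @export
summary_reproduction <- function(summaries = vessel_group_summaries()) {
  anova <- purrr::map_dfr(unique(summaries$parameter), function(p) {
    fit <- anova_from_summary(
      dplyr::filter(summaries, .data$parameter == p) |>
        dplyr::rename(label = "group"))
    tibble(parameter = p, f_statistic = fit$f_statistic,
           p_value = fit$p_value)
  })
  mean_of <- function(p, g) {
    summaries$mean[summaries$parameter == p & summaries$group == g]
  }
  wall <- purrr::map_dfr(unique(summaries$group), function(g) {
    tibble(group = g,
           awt_um = (mean_of("RAOD", g) - mean_of("RALD", g)) / 2,
           vwt_um = (mean_of("RVOD", g) - mean_of("RVLD", g)) / 2)
  })
  list(anova = anova, wall_identity = wall)
}
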