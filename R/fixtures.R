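#' Packaged reference cohort summaries
#'
#' The package ships the published per-group `(n, mean, SD)` summaries of the
#' retinal vessel parameters (RALD, RAOD, RVLD, RVOD, AVR, AWT, VWT) for the
#' three study groups — ischemic heart disease (IHD, n = 91), microvascular
#' angina (MA, n = 29) and controls (n = 66) — together with the clinical
#' covariate profile (age, sex, diabetes, smoking, hypertension,
#' dyslipidemia, BMI). These drive the summary-statistic ANOVA reproduction
#' and parameterize the synthetic cohort generator, so no clinical data are
#' needed.
#'
#' @return `vessel_group_summaries()`: a tibble with columns `parameter`,
#'   `group`, `n`, `mean`, `sd`. `covariate_profile()`: a tibble with columns
#'   `variable`, `group`, `type`, `n`, `count`, `mean`, `sd`.
#' @examples
#' vessel_group_summaries()
#' @export
vessel_group_summaries <- function() {
  readr::read_csv(
    system.file("extdata", "vessel_group_summaries.csv", package = "octfwhm"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' @rdname vessel_group_summaries
#' @export
covariate_profile <- function() {
  readr::read_csv(
    system.file("extdata", "covariate_profile.csv", package = "octfwhm"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' @rdname vessel_group_summaries
#' @return `enrollment_rosters()`: a named list of two
#'   [enrollment_roster()]s, `patients` (135 screened, 15 withdrawn for
#'   unclear media or by request) and `controls` (76 screened, 8 withdrawn
#'   for unclear media, 2 for a positive exercise test).
#' @export
enrollment_rosters <- function() {
  list(
    patients = enrollment_roster(135, c(media_or_request = 15)),
    controls = enrollment_roster(76, c(media = 8, positive_test = 2))
  )
}
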