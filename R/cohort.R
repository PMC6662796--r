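#' Arteriovenous ratio of paired vessel measurements
#'
#' Per-subject ratio of the arterial to the accompanying venular diameter.
#' The ratio is always formed within a subject (never as a ratio of group
#' means). Which diameter enters the ratio is configurable: the default
#' `"lumen"` uses the blood-column caliber (RALD / RVLD), the classic
#' fundus-photography convention; `"outer"` uses RAOD / RVOD.
#'
#' @param artery,vein One-row `vessel_measurement` tibbles (see
#'   [measure_vessel()]) of the matching kinds, or plain lists/rows with
#'   `kind`, `outer_um`, `lumen_um`.
#' @param definition `"lumen"` (default) or `"outer"`.
#' @return The dimensionless AVR.
#' @examples
#' a <- measure_vessel(make_profile(synth_vessel_spec(seed = 1))$profile, "artery")
#' v <- measure_vessel(make_profile(synth_vessel_spec(
#'   true_outer = 190, true_lumen = 153, seed = 2))$profile, "vein")
#' compute_avr(a, v)
#' @export
compute_avr <- function(artery, vein, definition = c("lumen", "outer")) {
  definition <- match.arg(definition)
  get <- function(m, want_kind, name) {
    if (!is.list(m) || is.null(m$kind) || is.null(m$lumen_um) ||
        is.null(m$outer_um)) {
      stop_octfwhm(sprintf("`%s` must be a vessel measurement.", name),
                   "validation")
    }
    if (!identical(as.character(m$kind[1L]), want_kind)) {
      stop_octfwhm(sprintf("`%s` must have kind '%s'.", name, want_kind),
                   "validation")
    }
    m
  }
  a <- get(artery, "artery", "artery")
  v <- get(vein, "vein", "vein")
  num <- if (definition == "lumen") a$lumen_um[1L] else a$outer_um[1L]
  den <- if (definition == "lumen") v$lumen_um[1L] else v$outer_um[1L]
  if (!is.finite(den) || den <= 0) {
    stop_octfwhm("Venular diameter must be positive.", "validation")
  }
  num / den
}

#' Eye-selection rule
#'
#' The right eye is measured when gradable; otherwise the left eye is
#' measured instead; when neither eye is gradable the subject is excluded.
#' Vectorized over subjects.
#'
#' @param right_ok,left_ok Logical: is the eye gradable (clear media, full
#'   peripapillary visualization)?
#' @return Character vector: `"right"`, `"left"` or `"none"`.
#' @examples
#' select_eye(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE))
#' @export
select_eye <- function(right_ok, left_ok) {
  stopifnot(is.logical(right_ok), is.logical(left_ok),
            length(right_ok) == length(left_ok))
  dplyr::case_when(right_ok ~ "right", left_ok ~ "left", TRUE ~ "none")
}

#' Enrollment roster and filter
#'
#' Tracks screened subjects and withdrawal categories; the enrolled count is
#' screened minus all withdrawals.
#'
#' @param screened Number of subjects screened.
#' @param withdrawals Named (or unnamed) non-negative counts of withdrawals
#'   by reason.
#' @return For `enrollment_roster()`, an `enrollment_roster` object; for
#'   `apply_enrollment()`, the enrolled count.
#' @examples
#' apply_enrollment(enrollment_roster(135, c(media_or_request = 15)))
#' @export
enrollment_roster <- function(screened, withdrawals = numeric(0)) {
  check_number(screened, "screened")
  if (screened < 0 || screened != round(screened)) {
    stop_octfwhm("`screened` must be a non-negative integer.", "validation")
  }
  if (length(withdrawals) &&
      (anyNA(withdrawals) || any(withdrawals < 0) ||
       any(withdrawals != round(withdrawals)))) {
    stop_octfwhm("Withdrawal counts must be non-negative integers.",
                 "validation")
  }
  structure(list(screened = as.integer(screened),
                 withdrawals = withdrawals,
                 enrolled = as.integer(screened - sum(withdrawals))),
            class = "enrollment_roster")
}

#' @rdname enrollment_roster
#' @param roster An `enrollment_roster`.
#' @export
apply_enrollment <- function(roster) {
  stopifnot(inherits(roster, "enrollment_roster"))
  out <- roster$screened - sum(roster$withdrawals)
  if (out < 0) {
    stop_octfwhm("More withdrawals than screened subjects.", "validation")
  }
  as.integer(out)
}

subject_columns <- c(
  "subject_id", "group", "age", "sex", "diabetes", "smoker", "hypertension",
  "dyslipidemia", "bmi", "eye_used", "raod_um", "rald_um", "rvod_um",
  "rvld_um", "awt_um", "vwt_um", "avr", "severity_grade"
)

#' Assemble a subject record
#'
#' Combines one subject's arterial and venular measurements with clinical
#' covariates into the flat per-subject row used by the cohort analyses.
#' AVR and wall thicknesses are derived from the stored diameters.
#'
#' @param subject_id Identifier string.
#' @param group One of `"IHD"`, `"MA"`, `"control"`.
#' @param artery,vein One-row `vessel_measurement`s of the matching kinds.
#' @param age,bmi Numeric covariates.
#' @param sex `"male"` or `"female"`.
#' @param diabetes,smoker,hypertension,dyslipidemia Logical covariates.
#' @param eye_used `"right"` or `"left"` (see [select_eye()]).
#' @param severity_grade Supplied ordinal disease-severity grade, or `NA`.
#' @param avr_definition Passed to [compute_avr()].
#' @return A one-row tibble with the standard subject columns.
#' @export
subject_record <- function(subject_id, group, artery, vein, age, sex,
                           diabetes = FALSE, smoker = FALSE,
                           hypertension = FALSE, dyslipidemia = FALSE,
                           bmi = NA_real_, eye_used = "right",
                           severity_grade = NA_integer_,
                           avr_definition = c("lumen", "outer")) {
  group <- match.arg(group, c("IHD", "MA", "control"))
  avr <- compute_avr(artery, vein, definition = avr_definition)
  tibble(
    subject_id = as.character(subject_id), group = group,
    age = age, sex = sex, diabetes = diabetes, smoker = smoker,
    hypertension = hypertension, dyslipidemia = dyslipidemia, bmi = bmi,
    eye_used = eye_used,
    raod_um = artery$outer_um[1L], rald_um = artery$lumen_um[1L],
    rvod_um = vein$outer_um[1L], rvld_um = vein$lumen_um[1L],
    awt_um = (artery$outer_um[1L] - artery$lumen_um[1L]) / 2,
    vwt_um = (vein$outer_um[1L] - vein$lumen_um[1L]) / 2,
    avr = avr, severity_grade = as.integer(severity_grade)
  )
}

#' Read / write subject tables
#'
#' CSV round-trip of the per-subject records (see [subject_record()] for the
#' column set). Reading recomputes nothing; writing stores full precision.
#'
#' @param path CSV path.
#' @return `read_subjects()` returns a tibble of subject records.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) {
    stop_octfwhm(sprintf("Subject file '%s' does not exist.", path), "input")
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(subject_columns, names(out))
  if (length(missing)) {
    stop_octfwhm(sprintf("Subject table is missing columns: %s",
                         paste(missing, collapse = ", ")), "validation")
  }
  out
}

#' @rdname read_subjects
#' @param subjects A tibble of subject records.
#' @export
write_subjects <- function(subjects, path) {
  readr::write_csv(subjects, path, progress = FALSE)
  invisible(path)
}
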