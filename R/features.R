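#' Validate a cohort table
#'
#' Checks the per-subject invariants required by the downstream feature
#' maps: positive baseline BMI, intake, and expenditure; a positive
#' follow-up interval whenever a follow-up BMI is present; unique ids; sex
#' coded \code{"man"}/\code{"woman"}.
#'
#' @param subjects data frame with columns \code{subject_id}, \code{age},
#'   \code{sex}, \code{bmi_baseline}, \code{energy_intake_kcal},
#'   \code{energy_expenditure_mets_h} and optionally \code{bmi_followup},
#'   \code{followup_years} (NA where a subject was lost to follow-up).
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_subjects <- function(subjects) {
  req <- c("subject_id", "age", "sex", "bmi_baseline",
           "energy_intake_kcal", "energy_expenditure_mets_h")
  missing_cols <- setdiff(req, names(subjects))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject_id values")
  if (!all(subjects$sex %in% c("man", "woman"))) {
    stop("sex must be coded 'man' or 'woman'")
  }
  check_pos <- function(col) {
    v <- subjects[[col]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop(sprintf("subject '%s': %s must be strictly positive (got %s)",
                   subjects$subject_id[bad[1L]], col, format(v[bad[1L]])))
    }
  }
  check_pos("bmi_baseline")
  check_pos("energy_intake_kcal")
  check_pos("energy_expenditure_mets_h")
  if ("bmi_followup" %in% names(subjects)) {
    has_fu <- !is.na(subjects$bmi_followup)
    if (!"followup_years" %in% names(subjects)) {
      stop("bmi_followup present without followup_years")
    }
    iv <- subjects$followup_years[has_fu]
    if (any(is.na(iv) | iv <= 0)) {
      stop("followup_years must be positive wherever bmi_followup is present")
    }
  }
  subjects
}

#' Map cohort variables to DEA inputs and output
#'
#' Each subject becomes one decision-making unit with inputs
#' \code{(energy expenditure [METs-h/day], 1 / energy intake [day/kcal])}
#' and output \code{1 / baseline BMI} (m\eqn{^2}/kg).  Taking inverses makes
#' "less intake" and "lower BMI" point in the efficiency-improving
#' direction required by the input-oriented model.
#'
#' @inheritParams validate_subjects
#' @return A [dmu_set()] preserving subject ids.
#' @export
build_dea_frame <- function(subjects) {
  subjects <- validate_subjects(subjects)
  dmu_set(
    ids     = subjects$subject_id,
    inputs  = cbind(subjects$energy_expenditure_mets_h,
                    1 / subjects$energy_intake_kcal),
    outputs = cbind(1 / subjects$bmi_baseline)
  )
}

#' Classify BMI into underweight / normal / overweight
#'
#' Half-open WHO-style categories: underweight below 18.5 kg/m2, normal
#' from 18.5 up to (not including) 25, overweight at 25 and above.
#'
#' @param bmi numeric vector of positive BMI values (kg/m2).
#' @return factor with levels \code{underweight}, \code{normal},
#'   \code{overweight}.
#' @examples
#' classify_bmi(c(18.4, 18.5, 24.99, 25))
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) stop("BMI must be strictly positive")
  cut(bmi, breaks = c(0, 18.5, 25, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight"))
}

#' Yearly change in BMI
#'
#' \code{(bmi_followup - bmi_baseline) / followup_years}, in kg/m2/year.
#' Subjects without follow-up get \code{NA} unless \code{require_complete}
#' is \code{TRUE}, in which case missing follow-up raises an error naming
#' the first offending subject.
#'
#' @inheritParams validate_subjects
#' @param require_complete error on missing follow-up instead of NA.
#' @return numeric vector aligned with the rows of \code{subjects}.
#' @export
yearly_bmi_change <- function(subjects, require_complete = FALSE) {
  subjects <- validate_subjects(subjects)
  if (!"bmi_followup" %in% names(subjects)) {
    if (require_complete) stop("no follow-up columns in cohort table")
    return(rep(NA_real_, nrow(subjects)))
  }
  miss <- is.na(subjects$bmi_followup) | is.na(subjects$followup_years)
  if (require_complete && any(miss)) {
    stop("subject '", subjects$subject_id[which(miss)[1L]],
         "': follow-up BMI or interval missing")
  }
  ifelse(miss, NA_real_,
         (subjects$bmi_followup - subjects$bmi_baseline) / subjects$followup_years)
}

#' Restrict to subjects eligible for the BMI-change analysis
#'
#' Keeps subjects whose baseline BMI is in the normal range (18.5 to <25
#' kg/m2) and who have follow-up data; underweight and overweight subjects
#' are excluded from the change analysis.  Idempotent; may return zero
#' rows.
#'
#' @inheritParams validate_subjects
#' @return Subset of \code{subjects} (same columns).
#' @export
change_analysis_filter <- function(subjects) {
  subjects <- validate_subjects(subjects)
  if (!"bmi_followup" %in% names(subjects)) return(subjects[0, , drop = FALSE])
  keep <- classify_bmi(subjects$bmi_baseline) == "normal" &
    !is.na(subjects$bmi_followup) & !is.na(subjects$followup_years)
  subjects[keep, , drop = FALSE]
}

#' Read / write the cohort CSV
#'
#' Columns: \code{subject_id, age, sex (M/F), bmi_baseline,
#' energy_intake_kcal, energy_expenditure_mets_h, bmi_followup,
#' followup_years}; missing values are empty cells.  Additional columns
#' (e.g. \code{gps}, \code{efficiency}) are carried through.
#'
#' @param path file path.
#' @return \code{read_cohort_csv}: validated data frame with sex expanded
#'   to \code{"man"}/\code{"woman"}.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("sex" %in% names(df) && all(df$sex %in% c("M", "F"))) {
    df$sex <- ifelse(df$sex == "F", "woman", "man")
  }
  validate_subjects(df)
}

#' @rdname read_cohort_csv
#' @param subjects cohort data frame to serialise.
#' @export
write_cohort_csv <- function(subjects, path) {
  out <- subjects
  out$sex <- ifelse(out$sex == "woman", "F", "M")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
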