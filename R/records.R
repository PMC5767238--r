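# Analysis records: one row per subject-visit, carrying identifiers,
# covariates, diagnosis and factor scores. Age is centered at 63 years
# (the cohort average), with ages carried at two-decimal precision.

AGE_CENTER_YEARS <- 63

#' Assemble and validate analysis records
#'
#' Validates the subject-visit table used by the longitudinal models and
#' (re)computes \code{age_centered = round(age_years, 2) - 63}.
#'
#' @param df data.frame with at least \code{subject_id}, \code{visit},
#'   \code{age_years}, \code{sex} ("male"/"female"), \code{literacy},
#'   \code{dx} ("CH"/"eMCI") and one column per outcome of interest.
#'   Optional: \code{cesd_total}, \code{anxiety_flag}, \code{sleep_score}.
#' @return The validated data.frame, classed \code{analysis_records}.
#' @export
analysis_records <- function(df) {
  need <- c("subject_id", "visit", "age_years", "sex", "literacy", "dx")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be coded 'male'/'female'")
  if (!all(df$dx %in% c("CH", "eMCI")))
    stop("dx must be coded 'CH'/'eMCI'")
  if (any(is.na(df$age_years)))
    stop("age_years must be complete")
  # sex and dx must be constant within subject (dx is the follow-up
  # consensus label, carried on every record of the subject)
  for (col in c("sex", "dx")) {
    per <- tapply(df[[col]], df$subject_id, function(v) length(unique(v)))
    if (any(per > 1L))
      stop(col, " varies within subject(s): ",
           paste(head(names(per)[per > 1L], 3), collapse = ", "))
  }
  df$age_centered <- round(df$age_years, 2) - AGE_CENTER_YEARS
  class(df) <- c("analysis_records", "data.frame")
  df
}
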