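# ANCOVA-adjusted group comparisons: group means evaluated at the
# covariate grand means from a linear model with group + covariates.

#' Covariate-adjusted group means for an outcome
#'
#' Fits \code{outcome ~ dx + covariates} by least squares and reports
#' each group's adjusted mean (the model prediction at the grand mean of
#' every covariate), its standard error, and the p-value of the group
#' effect. The standard use adjusts baseline factor scores for age, sex
#' and literacy.
#'
#' @param records data.frame with \code{dx} and the covariate columns;
#'   typically one row per subject (e.g. the baseline visit).
#' @param outcome Outcome column name.
#' @param covariates Covariate column names; \code{sex} is coded
#'   male = 1 internally. Defaults to \code{c("age_years", "sex",
#'   "literacy")}.
#' @return data.frame with one row per group (\code{dx}, adjusted mean,
#'   SE) carrying the group-effect p-value and the fitted \code{lm} as
#'   attributes \code{"p_value"} and \code{"model"}.
#' @export
adjusted_group_means <- function(records, outcome,
                                 covariates = c("age_years", "sex", "literacy")) {
  df <- as.data.frame(records)
  if (!(outcome %in% names(df))) stop("no outcome column '", outcome, "'")
  if (length(unique(df$dx)) < 2L)
    stop("both diagnosis groups must be present")
  df$dx_emci <- as.numeric(df$dx == "eMCI")
  covs <- character(0)
  for (cv in covariates) {
    col <- if (cv == "sex") {
      df$sex_male <- as.numeric(df$sex == "male"); "sex_male"
    } else cv
    if (length(unique(df[[col]])) < 2L)
      stop("covariate '", cv, "' is constant")
    covs <- c(covs, col)
  }
  form <- stats::as.formula(paste(outcome, "~ dx_emci +",
                                  paste(covs, collapse = " + ")))
  fit <- lm(form, data = df)
  V <- vcov(fit)
  grand <- vapply(covs, function(cl) mean(df[[cl]]), numeric(1))
  res <- lapply(c(CH = 0, eMCI = 1), function(g) {
    cvec <- c(1, g, grand)  # intercept, group code, covariate grand means
    est <- sum(cvec * coef(fit))
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    c(mean = est, se = se)
  })
  p_group <- summary(fit)$coefficients["dx_emci", "Pr(>|t|)"]
  out <- data.frame(dx = c("CH", "eMCI"),
                    adjusted_mean = c(res$CH["mean"], res$eMCI["mean"]),
                    se = c(res$CH["se"], res$eMCI["se"]),
                    stringsAsFactors = FALSE)
  attr(out, "p_value") <- p_group
  attr(out, "model") <- fit
  out
}
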