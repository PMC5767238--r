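# Model-selection procedure for the trajectory models: start from the
# base model (age, sex, literacy, diagnosis), test each diagnosis
# interaction, retain only significant ones, refit by REML, then re-run
# the final model with the secondary covariates (depression, anxiety,
# sleep) as fixed effects.

#' Select and fit the final trajectory model for one outcome
#'
#' Fits the base random-intercept model
#' \code{outcome ~ age_centered + sex + literacy + dx + (1 | subject)},
#' tests the diagnosis-by-age, diagnosis-by-sex and diagnosis-by-literacy
#' interactions one at a time at level \code{alpha} (Wald test from the
#' REML fit), retains the significant ones, and refits the final model by
#' REML. A secondary refit adds depressive symptoms, anxiety and sleep
#' quality as fixed effects and reports whether any is significant.
#'
#' @param records An \code{\link{analysis_records}} data.frame.
#' @param outcome Outcome column name.
#' @param alpha Significance threshold for interaction retention
#'   (default 0.05, unadjusted).
#' @param bonferroni Divide \code{alpha} by the number of interaction
#'   tests? Default \code{FALSE} (no multiple-comparison adjustment).
#' @param secondary Run the secondary-covariate refit? Requires
#'   \code{cesd_total}, \code{anxiety_flag}, \code{sleep_score} columns.
#' @return An object of class \code{ri_lmm_selection}: list with the
#'   final \code{spec}, the final \code{fit}, the per-interaction test
#'   table \code{interaction_tests}, and (optionally)
#'   \code{secondary_fit} plus \code{secondary_significant}.
#' @export
select_final_model <- function(records, outcome, alpha = 0.05,
                               bonferroni = FALSE, secondary = TRUE) {
  base_terms <- c("intercept", "age_centered", "sex", "literacy", "dx")
  candidates <- c("age_centered:dx", "sex:dx", "literacy:dx")
  thr <- if (bonferroni) alpha / length(candidates) else alpha

  tests <- data.frame(term = candidates, estimate = NA_real_, p = NA_real_,
                      retained = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(candidates)) {
    sp <- model_spec(outcome, c(base_terms, candidates[k]))
    ft <- fit_random_intercept_lmm(records, sp)
    row <- ft$coefficients[ft$coefficients$term == candidates[k], ]
    tests$estimate[k] <- row$estimate
    tests$p[k] <- row$p
    tests$retained[k] <- is.finite(row$p) && row$p < thr
  }

  final_terms <- c(base_terms, tests$term[tests$retained])
  final_spec <- model_spec(outcome, final_terms)
  final_fit <- fit_random_intercept_lmm(records, final_spec)

  out <- list(spec = final_spec, fit = final_fit,
              interaction_tests = tests, alpha = thr)
  if (secondary &&
      all(c("cesd_total", "anxiety_flag", "sleep_score") %in% names(records))) {
    sec_spec <- model_spec(outcome, final_terms,
                           secondary_terms = c("cesd", "anxiety", "sleep"))
    sec_fit <- fit_random_intercept_lmm(records, sec_spec)
    sec <- sec_fit$coefficients
    sec <- sec[sec$term %in% c("cesd", "anxiety", "sleep"), ]
    out$secondary_fit <- sec_fit
    out$secondary_significant <- sec$term[sec$p < thr]
  }
  structure(out, class = "ri_lmm_selection")
}

#' @export
print.ri_lmm_selection <- function(x, ...) {
  cat("Model selection for outcome:", x$fit$spec$outcome, "\n")
  cat("Interaction tests (alpha =", x$alpha, "):\n")
  tab <- x$interaction_tests
  tab$estimate <- round(tab$estimate, 3)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  cat("\nFinal model:\n")
  print(x$fit)
  if (!is.null(x$secondary_significant)) {
    cat("Secondary covariates significant:",
        if (length(x$secondary_significant))
          paste(x$secondary_significant, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Render a fit as a publication-style coefficient table
#'
#' @param fit An \code{ri_lmm}.
#' @return Character vector of formatted lines ("beta (SE)  95% CI  p").
#' @export
format_coef_table <- function(fit) {
  tab <- fit$coefficients
  sprintf("%-18s %7.3f (%.3f)  [%.3f, %.3f]  p=%s",
          tab$term, tab$estimate, tab$se, tab$ci_lower, tab$ci_upper,
          format.pval(tab$p, digits = 2, eps = 1e-4))
}
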