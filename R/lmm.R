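# Random-intercept linear mixed models of factor-score trajectories,
# fitted by REML through lme4. The random part is always exactly a
# subject-specific intercept; growth (random-slope) terms are
# deliberately out of scope.

FIXED_TERM_SET <- c("intercept", "age_centered", "sex", "literacy", "dx",
                    "age_centered:dx", "sex:dx", "literacy:dx")
SECONDARY_TERM_SET <- c("cesd", "anxiety", "sleep")

#' Specify a random-intercept trajectory model
#'
#' @param outcome Outcome column name (e.g. \code{"semantic"},
#'   \code{"fluency"}).
#' @param fixed_terms Ordered subset of \code{"intercept"},
#'   \code{"age_centered"}, \code{"sex"}, \code{"literacy"}, \code{"dx"},
#'   \code{"age_centered:dx"}, \code{"sex:dx"}, \code{"literacy:dx"}.
#'   Any interaction requires both main effects.
#' @param secondary_terms Subset of \code{"cesd"}, \code{"anxiety"},
#'   \code{"sleep"} added as fixed effects.
#' @param reml Fit by REML (default) or ML.
#' @param standardize_literacy Z-score the literacy covariate over the
#'   analysis sample (default) or use the raw score.
#' @return A \code{model_spec} object.
#' @export
model_spec <- function(outcome,
                       fixed_terms = c("intercept", "age_centered", "sex",
                                       "literacy", "dx"),
                       secondary_terms = character(0),
                       reml = TRUE,
                       standardize_literacy = TRUE) {
  bad <- setdiff(fixed_terms, FIXED_TERM_SET)
  if (length(bad)) stop("unknown fixed terms: ", paste(bad, collapse = ", "))
  bad2 <- setdiff(secondary_terms, SECONDARY_TERM_SET)
  if (length(bad2)) stop("unknown secondary terms: ", paste(bad2, collapse = ", "))
  for (ia in grep(":", fixed_terms, value = TRUE)) {
    mains <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (!all(mains %in% fixed_terms))
      stop("interaction ", ia, " requires both main effects in fixed_terms")
  }
  structure(list(outcome = outcome, fixed_terms = fixed_terms,
                 secondary_terms = secondary_terms, reml = isTRUE(reml),
                 standardize_literacy = isTRUE(standardize_literacy)),
            class = "model_spec")
}

# Map canonical term labels onto model-frame columns. Coding reproduces
# the reported sign conventions: dx eMCI = 1 / CH = 0, sex male = 1 /
# female = 0.
term_column <- function(term) {
  switch(term,
         intercept = "1",
         age_centered = "age_centered",
         sex = "sex_male",
         literacy = "literacy_cov",
         dx = "dx_emci",
         "age_centered:dx" = "age_centered:dx_emci",
         "sex:dx" = "sex_male:dx_emci",
         "literacy:dx" = "literacy_cov:dx_emci",
         cesd = "cesd_total",
         anxiety = "anxiety_flag",
         sleep = "sleep_score",
         stop("no column mapping for term ", term))
}

prepare_model_frame <- function(records, spec) {
  df <- as.data.frame(records)
  if (!(spec$outcome %in% names(df)))
    stop("records lack outcome column '", spec$outcome, "'")
  df$sex_male <- as.numeric(df$sex == "male")
  df$dx_emci <- as.numeric(df$dx == "eMCI")
  lit_center <- 0; lit_scale <- 1
  if (spec$standardize_literacy) {
    lit_center <- mean(df$literacy, na.rm = TRUE)
    lit_scale <- sd(df$literacy, na.rm = TRUE)
    if (is.na(lit_scale) || lit_scale == 0)
      stop("literacy is constant; cannot standardize")
  }
  df$literacy_cov <- (df$literacy - lit_center) / lit_scale
  attr(df, "literacy_center") <- lit_center
  attr(df, "literacy_scale") <- lit_scale
  df
}

build_fixed_formula <- function(spec) {
  terms <- c(spec$fixed_terms, spec$secondary_terms)
  rhs <- vapply(setdiff(terms, "intercept"), term_column, "")
  has_int <- "intercept" %in% terms
  rhs_str <- paste(c(if (!has_int) "0", rhs), collapse = " + ")
  if (!nzchar(rhs_str)) rhs_str <- "1"
  list(fixed = paste(spec$outcome, "~", rhs_str),
       labels = c(if (has_int) "intercept", setdiff(terms, "intercept")))
}

#' Fit a random-intercept linear mixed model
#'
#' Fits \code{outcome ~ fixed terms + (1 | subject_id)} by REML (default)
#' through \pkg{lme4}, with diagnosis coded eMCI = 1 and sex coded
#' male = 1. Reports Wald-type standard errors, 95\% confidence intervals
#' and two-sided p-values using a residual degrees-of-freedom convention
#' (df = observations - fixed-effect count), plus the variance components
#' (subject-intercept variance tau^2 and residual variance sigma^2).
#' Non-convergence and singular (boundary) variance fits are flagged on
#' the returned object, never silently dropped.
#'
#' @param records An \code{\link{analysis_records}} data.frame (or any
#'   data.frame with the required columns).
#' @param spec A \code{\link{model_spec}}; alternatively pass the outcome
#'   name and the default base model is used.
#' @return An object of class \code{ri_lmm} with \code{print},
#'   \code{summary}, \code{coef}, \code{confint}, \code{predict},
#'   \code{residuals}, \code{simulate} and \code{plot} methods.
#' @examples
#' cfg <- sim_cohort_config("Fluency", n_ch = 40, n_emci = 20, seed = 7)
#' rec <- simulate_cohort_scores(cfg)
#' fit <- fit_random_intercept_lmm(rec, model_spec("fluency",
#'   c("intercept", "age_centered", "sex", "literacy", "dx",
#'     "age_centered:dx")))
#' coef(fit)
#' @export
fit_random_intercept_lmm <- function(records, spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  df <- prepare_model_frame(records, spec)
  if (length(unique(df$subject_id)) < 2L)
    stop("need at least 2 subjects")
  ff <- build_fixed_formula(spec)

  # rank check on the fixed-effect design before fitting
  X <- model.matrix(stats::as.formula(paste("~", sub("^[^~]+~", "", ff$fixed))),
                    df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }

  form <- stats::as.formula(paste(ff$fixed, "+ (1 | subject_id)"))
  # lme4's boundary chatter is re-reported through our own flags below
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = spec$reml,
                    control = lme4::lmerControl(
                      calc.derivs = FALSE,
                      # single-visit designs are legal: the intercept
                      # variance is then confounded and sits on the boundary
                      check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore")))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- length(msgs) == 0L
  boundary <- lme4::isSingular(fit, tol = 1e-4)

  beta <- lme4::fixef(fit)
  # vcov can fail on fully degenerate (zero-variance) fits; Wald SEs are
  # then undefined and reported as NA
  se <- tryCatch(suppressWarnings(sqrt(diag(as.matrix(vcov(fit))))),
                 error = function(e) rep(NA_real_, length(beta)))
  n_obs <- nrow(df)
  dfree <- n_obs - length(beta)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = dfree)
  crit <- qt(0.975, df = dfree)
  # map lme4's coefficient order (mains before interactions) back onto
  # the canonical term labels
  col_of <- vapply(ff$labels, function(tm)
    if (tm == "intercept") "(Intercept)" else term_column(tm), "")
  term_labels <- ff$labels[match(names(beta), col_of)]
  if (anyNA(term_labels))
    stop("internal error: could not label coefficients ",
         paste(names(beta)[is.na(term_labels)], collapse = ", "))
  coefs <- data.frame(term = term_labels,
                      estimate = unname(beta), se = unname(se),
                      ci_lower = unname(beta - crit * se),
                      ci_upper = unname(beta + crit * se),
                      t = unname(tval), df = dfree, p = unname(pval),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "subject_id"][1]
  sigma2 <- vc$vcov[vc$grp == "Residual"][1]

  structure(list(coefficients = coefs, tau2 = tau2, sigma2 = sigma2,
                 converged = converged, boundary = boundary,
                 messages = msgs,
                 n_subjects = length(unique(df$subject_id)),
                 n_observations = n_obs,
                 spec = spec, formula = form, model = fit,
                 literacy_center = attr(df, "literacy_center"),
                 literacy_scale = attr(df, "literacy_scale")),
            class = "ri_lmm")
}

#' @export
print.ri_lmm <- function(x, digits = 3, ...) {
  cat("Random-intercept linear mixed model (",
      if (x$spec$reml) "REML" else "ML", ")\n", sep = "")
  cat("Outcome:", x$spec$outcome, " Subjects:", x$n_subjects,
      " Observations:", x$n_observations, "\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$ci_lower <- round(tab$ci_lower, digits)
  tab$ci_upper <- round(tab$ci_upper, digits)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "estimate", "se", "ci_lower", "ci_upper", "p")],
        row.names = FALSE)
  cat(sprintf("Variance components: tau^2 = %.4f, sigma^2 = %.4f\n",
              x$tau2, x$sigma2))
  if (!x$converged) cat("WARNING: optimizer reported non-convergence\n")
  if (x$boundary) cat("NOTE: variance estimate on the boundary (tau^2 ~ 0)\n")
  invisible(x)
}

#' @export
summary.ri_lmm <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.ri_lmm <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.ri_lmm <- function(object, parm, level = 0.95, ...) {
  tab <- object$coefficients
  if (level != 0.95) {
    crit <- qt(1 - (1 - level) / 2, df = tab$df[1])
    tab$ci_lower <- tab$estimate - crit * tab$se
    tab$ci_upper <- tab$estimate + crit * tab$se
  }
  out <- as.matrix(tab[, c("ci_lower", "ci_upper")])
  rownames(out) <- tab$term
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
predict.ri_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$model, ...))
  nd <- as.data.frame(newdata)
  nd$sex_male <- as.numeric(nd$sex == "male")
  nd$dx_emci <- as.numeric(nd$dx == "eMCI")
  nd$literacy_cov <- (nd$literacy - object$literacy_center) / object$literacy_scale
  predict(object$model, newdata = nd, allow.new.levels = TRUE, ...)
}

#' @export
residuals.ri_lmm <- function(object, ...) residuals(object$model, ...)

#' @export
simulate.ri_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$model, nsim = nsim, seed = seed, ...)
}

#' @export
plot.ri_lmm <- function(x, ...) {
  graphics::plot(stats::fitted(x$model), residuals(x$model),
                 xlab = "Fitted", ylab = "Residual",
                 main = paste("Residuals:", x$spec$outcome), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
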