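# Two-visit cohort simulator: factor scores drawn from the
# random-intercept linear mixed model
#   y_ij = x_ij' beta + b_i + e_ij,  b_i ~ N(0, tau^2), e_ij ~ N(0, sigma^2)
# with covariates drawn to mirror the study cohort (eMCI subjects older
# and more often male; literacy entering the linear predictor z-scored
# over the cohort).

#' Final-model fixed effects used as simulation ground truth
#'
#' The published final-model coefficients for the four factors: age
#' (centered, per year), sex (male = 1), literacy (standardized reading
#' standard score), diagnosis (eMCI = 1), and -- for the Semantic and
#' Fluency models -- the age-by-diagnosis interaction. Intercepts are 0
#' (factor scores are centered constructs).
#'
#' @return Named list of named coefficient vectors, one per factor.
#' @export
table_final_betas <- function() {
  list(
    Semantic = c(intercept = 0, age_centered = -0.001, sex = -0.09,
                 literacy = -0.28, dx = -0.07, `age_centered:dx` = -0.04),
    Syntax   = c(intercept = 0, age_centered = -0.01, sex = -0.24,
                 literacy = 0.75, dx = -0.19),
    Lexical  = c(intercept = 0, age_centered = -0.02, sex = -0.15,
                 literacy = -2.7, dx = 0.28),
    Fluency  = c(intercept = 0, age_centered = 0.01, sex = 0.57,
                 literacy = -0.70, dx = -0.23, `age_centered:dx` = -0.03)
  )
}

#' Configure a cohort simulation
#'
#' Defaults reproduce the study conditions: 200 cognitively healthy (CH)
#' and 64 early-MCI subjects, two visits a mean 2.0 (SD 1.5) years
#' apart, baseline ages ~ N(61.1, 6.5) for CH and N(64.2, 5.9) for eMCI
#' (overall approximately 62 +/- 6.5), male fraction 0.30 (CH) / 0.44
#' (eMCI), literacy (reading standard score) ~ N(106.7, 9.3),
#' random-intercept SD tau = 0.7 and residual SD sigma = 0.5. The fixed
#' effects default to the published final model of \code{factor}.
#'
#' @param factor Which factor's final model supplies the default
#'   \code{beta} ("Semantic", "Syntax", "Lexical" or "Fluency").
#' @param n_ch,n_emci Group sizes (each >= 2).
#' @param visits Visits per subject.
#' @param gap_mean,gap_sd Inter-visit gap distribution in years
#'   (truncated below at 0.25).
#' @param age_mean_ch,age_sd_ch,age_mean_emci,age_sd_emci Baseline age
#'   distributions by group.
#' @param male_p_ch,male_p_emci Male probability by group.
#' @param literacy_mean,literacy_sd Raw literacy score distribution.
#' @param beta Named fixed-effect vector over \code{intercept},
#'   \code{age_centered}, \code{sex}, \code{literacy}, \code{dx} and
#'   optionally \code{age_centered:dx}.
#' @param tau Random-intercept SD (>= 0).
#' @param sigma Residual SD (>= 0).
#' @param seed Optional integer seed; \code{NULL} draws from the current
#'   RNG stream.
#' @return A \code{sim_cohort_config} object.
#' @export
sim_cohort_config <- function(factor = "Semantic",
                              n_ch = 200L, n_emci = 64L,
                              visits = 2L, gap_mean = 2.0, gap_sd = 1.5,
                              age_mean_ch = 61.1, age_sd_ch = 6.5,
                              age_mean_emci = 64.2, age_sd_emci = 5.9,
                              male_p_ch = 0.30, male_p_emci = 0.44,
                              literacy_mean = 106.7, literacy_sd = 9.3,
                              beta = NULL,
                              tau = 0.7, sigma = 0.5, seed = NULL) {
  factor <- match.arg(factor, FACTOR_NAMES)
  if (is.null(beta)) beta <- table_final_betas()[[factor]]
  allowed <- c("intercept", "age_centered", "sex", "literacy", "dx",
               "age_centered:dx")
  bad <- setdiff(names(beta), allowed)
  if (length(bad))
    stop("beta terms do not map to model terms: ", paste(bad, collapse = ", "))
  if (n_ch < 2L || n_emci < 2L) stop("group sizes must be >= 2")
  if (visits < 1L) stop("visits must be >= 1")
  if (tau < 0 || sigma < 0) stop("tau and sigma must be non-negative")
  if (age_sd_ch <= 0 || age_sd_emci <= 0 || literacy_sd <= 0 || gap_sd < 0)
    stop("scale parameters must be positive")
  structure(list(factor = factor, n_ch = as.integer(n_ch),
                 n_emci = as.integer(n_emci), visits = as.integer(visits),
                 gap_mean = gap_mean, gap_sd = gap_sd,
                 age_mean_ch = age_mean_ch, age_sd_ch = age_sd_ch,
                 age_mean_emci = age_mean_emci, age_sd_emci = age_sd_emci,
                 male_p_ch = male_p_ch, male_p_emci = male_p_emci,
                 literacy_mean = literacy_mean, literacy_sd = literacy_sd,
                 beta = beta, tau = tau, sigma = sigma, seed = seed),
            class = "sim_cohort_config")
}

#' Simulate a longitudinal cohort of factor scores
#'
#' Draws covariates per \code{cfg}, then generates the outcome from the
#' random-intercept model \code{y = X beta + b_i + e} with
#' \code{b_i ~ N(0, tau^2)} and \code{e ~ N(0, sigma^2)}. The literacy
#' term of the linear predictor uses the cohort-z-scored literacy score
#' (the same convention \code{\link{fit_random_intercept_lmm}} applies
#' by default, so fitted literacy coefficients recover \code{beta}'s).
#' The secondary covariates (CES-D, anxiety flag, sleep score) are drawn
#' as opaque covariates with no effect on the outcome.
#'
#' @param cfg A \code{\link{sim_cohort_config}}.
#' @return An \code{\link{analysis_records}} data.frame with one row per
#'   subject-visit and the outcome in column
#'   \code{tolower(cfg$factor)}.
#' @export
simulate_cohort_scores <- function(cfg) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  if (!is.null(cfg$seed)) return(run_seeded(cfg$seed, function() sim_cohort_draw(cfg)))
  sim_cohort_draw(cfg)
}

sim_cohort_draw <- function(cfg) {
  n <- cfg$n_ch + cfg$n_emci
  dx <- c(rep("CH", cfg$n_ch), rep("eMCI", cfg$n_emci))
  emci <- as.numeric(dx == "eMCI")
  male_p <- ifelse(emci == 1, cfg$male_p_emci, cfg$male_p_ch)
  sex <- ifelse(rbinom(n, 1, male_p) == 1, "male", "female")
  age0 <- rnorm(n,
                mean = ifelse(emci == 1, cfg$age_mean_emci, cfg$age_mean_ch),
                sd = ifelse(emci == 1, cfg$age_sd_emci, cfg$age_sd_ch))
  literacy <- rnorm(n, cfg$literacy_mean, cfg$literacy_sd)
  # standardize over subject-visit rows, the same frame the fitting
  # function standardizes over, so literacy coefficients are recoverable
  lit_rows <- rep(literacy, cfg$visits)
  lit_z <- (literacy - mean(lit_rows)) / sd(lit_rows)
  b <- rnorm(n, 0, cfg$tau)
  anxiety <- rbinom(n, 1, 0.2)

  gaps <- matrix(0, n, cfg$visits)
  if (cfg$visits > 1L)
    gaps[, -1L] <- pmax(0.25, rnorm(n * (cfg$visits - 1L),
                                    cfg$gap_mean, cfg$gap_sd))
  ages <- age0 + t(apply(gaps, 1L, cumsum))
  if (cfg$visits == 1L) ages <- matrix(age0, n, 1L)

  bt <- function(term) if (term %in% names(cfg$beta)) cfg$beta[[term]] else 0
  rows <- vector("list", cfg$visits)
  for (j in seq_len(cfg$visits)) {
    age_c <- round(ages[, j], 2) - AGE_CENTER_YEARS
    mu <- bt("intercept") + bt("age_centered") * age_c +
      bt("sex") * (sex == "male") + bt("literacy") * lit_z +
      bt("dx") * emci + bt("age_centered:dx") * age_c * emci
    y <- mu + b + rnorm(n, 0, cfg$sigma)
    rows[[j]] <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)), visit = j,
      age_years = ages[, j], sex = sex, literacy = literacy, dx = dx,
      cesd_total = pmax(0, rnorm(n, 6, 5)),
      anxiety_flag = anxiety,
      sleep_score = pmin(100, pmax(0, rnorm(n, 70, 15))),
      outcome = y, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  names(df)[names(df) == "outcome"] <- tolower(cfg$factor)
  df <- df[order(df$subject_id, df$visit), ]
  rownames(df) <- NULL
  analysis_records(df)
}
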