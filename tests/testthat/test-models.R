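# Random-intercept mixed models, model selection, ANCOVA and
# correlations.

interaction_spec <- function(outcome) {
  model_spec(outcome, c("intercept", "age_centered", "sex", "literacy",
                        "dx", "age_centered:dx"))
}

test_that("fixed effects match the OLS oracle when tau^2 = 0", {
  # under a true tau of 0 the REML variance estimate hits the boundary in
  # a fair share of replicates; whenever it does, the mixed-model fixed
  # effects must coincide with ordinary least squares
  n_boundary <- 0L
  for (s in 21:26) {
    cfg <- sim_cohort_config("Semantic", n_ch = 80, n_emci = 40,
                             tau = 0, sigma = 0.5, seed = s)
    rec <- simulate_cohort_scores(cfg)
    fit <- fit_random_intercept_lmm(rec, interaction_spec("semantic"))
    if (!fit$boundary) next
    n_boundary <- n_boundary + 1L
    expect_equal(fit$tau2, 0, tolerance = 1e-10)
    df <- as.data.frame(rec)
    df$sex_male <- as.numeric(df$sex == "male")
    df$dx_emci <- as.numeric(df$dx == "eMCI")
    df$lit_z <- (df$literacy - mean(df$literacy)) / sd(df$literacy)
    ols <- lm(semantic ~ age_centered + sex_male + lit_z + dx_emci +
                age_centered:dx_emci, data = df)
    expect_equal(unname(coef(fit)),
                 unname(coef(ols)[c("(Intercept)", "age_centered", "sex_male",
                                    "lit_z", "dx_emci",
                                    "age_centered:dx_emci")]),
                 tolerance = 1e-6)
  }
  expect_gte(n_boundary, 2L)  # the boundary case actually occurred
})

test_that("a noise-free balanced group contrast is recovered exactly", {
  n <- 40
  df <- data.frame(subject_id = sprintf("S%02d", 1:n), visit = 1L,
                   age_years = 63, sex = rep(c("male", "female"), n / 2),
                   literacy = rep(c(100, 110), each = n / 2),
                   dx = rep(c("CH", "eMCI"), times = n / 2),
                   stringsAsFactors = FALSE)
  df$y <- as.numeric(df$dx == "eMCI")  # group means exactly 0 and 1
  rec <- analysis_records(df)
  fit <- fit_random_intercept_lmm(rec, model_spec("y", c("intercept", "dx")))
  expect_equal(coef(fit)[["dx"]], 1.0, tolerance = 1e-8)
  expect_equal(fit$sigma2, 0, tolerance = 1e-8)
})

test_that("rank-deficient designs fail loudly, naming the culprit", {
  cfg <- sim_cohort_config("Syntax", n_ch = 30, n_emci = 10, seed = 31)
  rec <- simulate_cohort_scores(cfg)
  rec$literacy <- 100  # constant literacy cannot be standardized
  expect_error(fit_random_intercept_lmm(rec, model_spec("syntax")), "constant")
  rec2 <- simulate_cohort_scores(cfg)
  rec2$sex <- ifelse(rec2$dx == "eMCI", "male", "female")  # sex == dx
  expect_error(fit_random_intercept_lmm(rec2, model_spec("syntax")),
               "collinear.*dx_emci|collinear.*sex_male")
})

test_that("single-visit data still fit, with the boundary flagged", {
  cfg <- sim_cohort_config("Lexical", n_ch = 40, n_emci = 20, visits = 1L,
                           seed = 41)
  rec <- simulate_cohort_scores(cfg)
  fit <- fit_random_intercept_lmm(rec, model_spec("lexical"))
  df <- as.data.frame(rec)
  df$sex_male <- as.numeric(df$sex == "male")
  df$dx_emci <- as.numeric(df$dx == "eMCI")
  df$lit_z <- (df$literacy - mean(df$literacy)) / sd(df$literacy)
  ols <- lm(lexical ~ age_centered + sex_male + lit_z + dx_emci, data = df)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-5)
})

test_that("selection keeps a simulated interaction and drops absent ones", {
  # strong interaction so one replicate decides reliably
  beta <- c(intercept = 0, age_centered = 0, sex = 0, literacy = 0,
            dx = 0, `age_centered:dx` = -0.3)
  cfg <- sim_cohort_config("Semantic", beta = beta, seed = 51)
  rec <- simulate_cohort_scores(cfg)
  sel <- select_final_model(rec, "semantic", secondary = TRUE)
  expect_true(sel$interaction_tests$retained[
    sel$interaction_tests$term == "age_centered:dx"])
  expect_true("age_centered:dx" %in% sel$spec$fixed_terms)
  # secondary refit ran and reports a (possibly empty) significant set
  expect_s3_class(sel$secondary_fit, "ri_lmm")
  expect_type(sel$secondary_significant, "character")
  expect_s3_class(sel$fit, "ri_lmm")
})

test_that("ANCOVA-adjusted means undo covariate confounding", {
  set.seed(61)
  n <- 400
  # eMCI subjects are older; the outcome depends on age only
  dx <- rep(c("CH", "eMCI"), each = n / 2)
  age <- rnorm(n, ifelse(dx == "eMCI", 68, 60), 3)
  df <- data.frame(subject_id = sprintf("S%03d", 1:n), visit = 1L,
                   age_years = age,
                   sex = sample(c("male", "female"), n, TRUE),
                   literacy = rnorm(n, 106, 9), dx = dx,
                   stringsAsFactors = FALSE)
  df$y <- -0.1 * (df$age_years - 63) + rnorm(n, 0, 0.1)
  raw_diff <- mean(df$y[dx == "eMCI"]) - mean(df$y[dx == "CH"])
  adj <- adjusted_group_means(df, "y")
  adj_diff <- adj$adjusted_mean[adj$dx == "eMCI"] - adj$adjusted_mean[adj$dx == "CH"]
  expect_lt(abs(adj_diff), 0.05)
  expect_gt(abs(raw_diff), 0.5)
  # orthogonal balanced design: adjustment changes nothing
  df2 <- df
  # period-4 covariate patterns: balanced across groups, mutually
  # non-collinear
  df2$age_years <- rep(c(60, 68, 60, 68), length.out = n)
  df2$sex <- rep(c("male", "male", "female", "female"), length.out = n)
  df2$literacy <- rep(c(100, 113, 113, 100), length.out = n)
  df2$y <- rnorm(n)
  adj2 <- adjusted_group_means(df2, "y")
  raw2 <- tapply(df2$y, df2$dx, mean)
  expect_equal(adj2$adjusted_mean, as.numeric(raw2[c("CH", "eMCI")]),
               tolerance = 1e-6)
  expect_error(adjusted_group_means(df[df$dx == "CH", ], "y"), "both")
})

test_that("rank correlations behave like Spearman's rho should", {
  set.seed(71)
  x <- rnorm(30); z <- rnorm(30)
  df <- data.frame(x = x, y = exp(x), z = z, w = -z)
  M <- correlation_matrix(df, c("x", "y", "z", "w"))
  expect_equal(M["x", "y"], 1.0)         # monotone transform
  expect_equal(M["z", "w"], -1.0)        # reversal
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 4))
  # 6-point hand dataset against the rank formula
  hx <- c(10, 20, 30, 40, 50, 60)
  hy <- c(1.2, 0.9, 2.5, 2.0, 3.3, 3.1)
  Mh <- correlation_matrix(data.frame(hx = hx, hy = hy), c("hx", "hy"))
  expect_equal(Mh["hx", "hy"], oracle_spearman(hx, hy))
  # invariance under a strictly monotone transform of one variable
  Mt <- correlation_matrix(data.frame(hx = log(hx), hy = hy), c("hx", "hy"))
  expect_equal(Mt["hx", "hy"], Mh["hx", "hy"])
  # constant variables give flagged NA cells
  Mc <- correlation_matrix(data.frame(a = rep(1, 10), b = 1:10), c("a", "b"))
  expect_true(is.na(Mc["a", "b"]))
  expect_identical(attr(Mc, "constant_vars"), "a")
})
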