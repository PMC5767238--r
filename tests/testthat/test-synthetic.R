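# Synthetic-data generators: determinism, composition and moment checks.

test_that("the default cohort reproduces the study composition", {
  rec <- simulate_cohort_scores(sim_cohort_config("Semantic", seed = 1))
  expect_equal(nrow(rec), 528L)
  expect_equal(length(unique(rec$subject_id)), 264L)
  per_subject <- rec[rec$visit == 1L, ]
  expect_equal(sum(per_subject$dx == "CH"), 200L)
  expect_equal(sum(per_subject$dx == "eMCI"), 64L)
  expect_s3_class(rec, "analysis_records")
  expect_equal(rec$age_centered, round(rec$age_years, 2) - 63)
  # eMCI group is older and more often male by construction
  expect_gt(mean(per_subject$age_years[per_subject$dx == "eMCI"]),
            mean(per_subject$age_years[per_subject$dx == "CH"]))
})

test_that("both generators are deterministic under a seed", {
  a <- simulate_cohort_scores(sim_cohort_config("Fluency", seed = 77))
  b <- simulate_cohort_scores(sim_cohort_config("Fluency", seed = 77))
  expect_identical(a, b)
  p <- random_transcript_plan(88)
  g1 <- generate_transcript(p)
  g2 <- generate_transcript(random_transcript_plan(88))
  expect_identical(g1$transcript, g2$transcript)
  expect_identical(write_chat(g1$transcript), write_chat(g2$transcript))
  # generation leaves the caller's RNG stream untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(generate_transcript(random_transcript_plan(89)))
  expect_identical(rnorm(1), before)
})

test_that("the noise-free limit collapses to the linear predictor", {
  beta <- c(intercept = 0.4, age_centered = -0.02, sex = 0.3,
            literacy = 0.1, dx = -0.5, `age_centered:dx` = -0.04)
  cfg <- sim_cohort_config("Semantic", n_ch = 30, n_emci = 10,
                           beta = beta, tau = 0, sigma = 0, seed = 99)
  rec <- simulate_cohort_scores(cfg)
  lit_z <- (rec$literacy - mean(rec$literacy)) / sd(rec$literacy)
  mu <- 0.4 - 0.02 * rec$age_centered + 0.3 * (rec$sex == "male") +
    0.1 * lit_z - 0.5 * (rec$dx == "eMCI") -
    0.04 * rec$age_centered * (rec$dx == "eMCI")
  expect_equal(rec$semantic, mu, tolerance = 1e-12)
})

test_that("variance components are recovered from simulated residuals", {
  # with tau = sigma the intraclass correlation is 0.5
  cfg <- sim_cohort_config("Syntax", n_ch = 1500, n_emci = 500,
                           beta = c(intercept = 0), tau = 0.6, sigma = 0.6,
                           seed = 111)
  rec <- simulate_cohort_scores(cfg)
  wide <- merge(rec[rec$visit == 1, c("subject_id", "syntax")],
                rec[rec$visit == 2, c("subject_id", "syntax")],
                by = "subject_id")
  icc <- cor(wide$syntax.x, wide$syntax.y)
  expect_equal(icc, 0.5, tolerance = 0.06)
  # between-subject variance of means: tau^2 + sigma^2/2
  v_means <- var(tapply(rec$syntax, rec$subject_id, mean))
  expect_equal(v_means, 0.36 + 0.18, tolerance = 0.06)
  # within-subject scatter recovers sigma^2
  v_within <- mean((wide$syntax.x - wide$syntax.y)^2) / 2
  expect_equal(v_within, 0.36, tolerance = 0.04)
})

test_that("unsatisfiable transcript plans are rejected", {
  pos <- cbind(noun = c(2L, 2L), verb = c(1L, 1L))
  expect_error(transcript_plan(pos, unique_words = 7, duration_s = 30),
               "unique_words > total_words")
  expect_error(transcript_plan(pos, unique_words = 1, duration_s = 30),
               "mandatory")
  expect_error(transcript_plan(pos, content_units = sprintf("u%d", 1:5),
                               unique_words = 6, duration_s = 30),
               "fewer planned nouns")
  # relations need two tokens in the C-unit
  expect_error(transcript_plan(cbind(noun = 1L),
                               relation_counts = cbind(embedding = 0L, total = 1L),
                               unique_words = 1, duration_s = 10),
               "fewer than 2 tokens")
  expect_error(transcript_plan(cbind(noun = 0L), unique_words = 0,
                               duration_s = 10), "content token or a maze event")
})

test_that("generated transcripts honour plan composition in detail", {
  p <- transcript_plan(
    pos_counts = cbind(noun = c(3L, 2L), verb = c(1L, 1L), pronoun = c(1L, 0L)),
    maze_counts = cbind(filled_pause = c(1L, 0L), repetition = c(0L, 1L),
                        unfilled_pause = c(1L, 0L)),
    relation_counts = cbind(embedding = c(1L, 0L), total = c(3L, 2L)),
    content_units = c("boy", "cookie"),
    unique_words = 6, duration_s = 45, seed = 4)
  g <- generate_transcript(p)
  ct <- tally_counts(g$transcript)
  expect_identical(ct$total_words, 8L)
  expect_identical(ct$unique_words, 6L)
  expect_identical(ct$nouns, 5L)
  expect_identical(ct$pronouns, 1L)
  expect_identical(ct$filled_pauses, 1L)
  expect_identical(ct$repetitions, 1L)
  expect_identical(ct$unfilled_pauses, 1L)
  expect_identical(ct$embedding_relations, 1L)
  expect_identical(ct$total_relations, 5L)
  expect_identical(ct$matched_content_units, 2L)
  expect_identical(sort(match_semantic_units(g$transcript)), c("boy", "cookie"))
  validate_transcript(g$transcript)
})
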