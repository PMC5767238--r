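# Count layer and derived discourse measures.

test_that("derive_features reproduces the worked formula example", {
  cs <- make_counts(nouns = 10, verbs = 5, pronouns = 5, adjectives = 3,
                    adverbs = 2, prepositions = 4, conjunctions = 1,
                    total_words = 50, unique_words = 30, n_utterances = 5,
                    filled_pauses = 2, repetitions = 1, revisions = 1,
                    embedding_relations = 3, total_relations = 12,
                    matched_content_units = 8, duration_s = 30)
  f <- derive_features(cs)
  expect_equal(f$pronoun_index, 5 / 15)
  expect_equal(f$verb_index, 1.0)
  expect_equal(f$proposition_density, 0.30)
  expect_equal(f$grammatical_complexity, 0.25)
  expect_equal(f$type_token_ratio, 0.60)
  expect_equal(f$maze_index, 0.8)
  expect_equal(f$mlu, 10.0)
  expect_equal(f$words_per_minute, 100.0)
  expect_equal(f$semantic_units_per_minute, 16.0)
  expect_equal(f$percent_nouns, 20.0)
  expect_equal(f$percent_verbs, 10.0)
  expect_equal(f$total_semantic_units, f$semantic_unit_count)
})

test_that("boundary ratios follow the zero-denominator policy", {
  # zero pronouns with nouns present: a defined 0, not missing
  f0 <- derive_features(make_counts(nouns = 5, total_words = 5,
                                    unique_words = 5, n_utterances = 1))
  expect_equal(f0$pronoun_index, 0)
  expect_equal(f0$maze_index, 0)
  # zero nouns+pronouns and zero relations: flagged missing, never 0
  f1 <- derive_features(make_counts(verbs = 3, total_words = 3,
                                    unique_words = 3, n_utterances = 1))
  expect_true(is.na(f1$pronoun_index))
  expect_true(is.na(f1$grammatical_complexity))
})

test_that("unfilled pauses enter the maze index only on request", {
  cs <- make_counts(nouns = 4, total_words = 4, unique_words = 4,
                    n_utterances = 2, filled_pauses = 1, unfilled_pauses = 3)
  expect_equal(derive_features(cs)$maze_index, 0.5)
  expect_equal(derive_features(cs, include_unfilled_pauses = TRUE)$maze_index, 2)
})

test_that("tally_counts counts only non-maze material as content", {
  doc <- c("@Duration: 30",
           "*PAR: &-um <the boy> [//] the girl is falling .",
           "%mor: determiner|the noun|girl verb|be verb|fall")
  ct <- tally_counts(parse_chat(doc),
                     as_content_lexicon(list(girl = "girl")))
  expect_identical(ct$total_words, 4L)
  expect_identical(ct$filled_pauses, 1L)
  expect_identical(ct$revisions, 1L)
  expect_identical(ct$nouns, 1L)
  expect_identical(ct$matched_content_units, 1L)
  # a transcript whose only material is maze is an empty sample
  maze_only <- c("@Duration: 30", "*PAR: &-um <the boy> [//] .")
  expect_error(tally_counts(parse_chat(maze_only)), "empty sample")
})

test_that("content-unit matching dedupes and supports multi-word triggers", {
  lex <- as_content_lexicon(list(boy = "boy", girl = "girl",
                                 stool_falling = "stool fall"))
  t1 <- make_simple_transcript(c("boy", "boy", "boy"))
  expect_identical(match_semantic_units(t1, lex), "boy")
  t2 <- make_simple_transcript(c("tree", "house"))
  expect_identical(match_semantic_units(t2, lex), character(0))
  # adjacent lemmas across the C-unit trigger the multi-word unit
  toks <- list(chat_token("stool", lemma = "stool", pos = "noun"),
               chat_token("falling", lemma = "fall", pos = "verb"))
  t3 <- chat_transcript("P1", "V1", 30, list(cunit(toks)))
  expect_identical(match_semantic_units(t3, lex), "stool_falling")
  # reversed order does not match
  t4 <- chat_transcript("P1", "V1", 30, list(cunit(rev(toks))))
  expect_identical(match_semantic_units(t4, lex), character(0))
})

test_that("maze-only insertions change only the maze index", {
  p <- random_transcript_plan(101)
  base <- generate_transcript(p)
  more <- p
  more$maze_counts[1, "filled_pause"] <- more$maze_counts[1, "filled_pause"] + 1L
  bumped <- generate_transcript(more)
  fb <- unclass(base$features); fm <- unclass(bumped$features)
  # one extra filled pause raises the maze index by exactly 1/n_utterances
  expect_equal(fm$maze_index - fb$maze_index, 1 / nrow(p$pos_counts))
  untouched <- setdiff(names(fb), "maze_index")
  expect_equal(fm[untouched], fb[untouched])
})

test_that("extraction equals the closed-form plan oracle exactly", {
  for (s in 201:215) {
    g <- generate_transcript(random_transcript_plan(s))
    got <- extract_features(g$transcript)
    expect_identical(unclass(got), unclass(g$features))
  }
})

test_that("feature tables round-trip through CSV with missing fields", {
  g1 <- generate_transcript(random_transcript_plan(301))
  path <- tempfile(fileext = ".csv")
  df <- write_feature_table(list(list(participant_id = "P1", visit_id = "V1",
                                      features = g1$features)), path)
  back <- read.csv(path)
  expect_equal(nrow(back), 1L)
  expect_equal(back$mlu, df$mlu)
  expect_equal(back$type_token_ratio, g1$features$type_token_ratio)
})
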