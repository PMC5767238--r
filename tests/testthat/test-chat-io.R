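# CHAT parsing, writing and reliability alignment.

fixture_doc <- function() {
  c("@Begin",
    "@Participants: PAR Participant, EXA Examiner",
    "@ID: PAR|P7|V2",
    "@Duration: 50.4",
    "*PAR: &-um <the boy> [//] the girl is falling .",
    "%mor: determiner|the noun|girl verb|be verb|fall",
    "%gra: 1|2|DET 2|4|SUBJ 3|4|AUX 4|2|COMP",
    "*PAR: she is on a stool .",
    "%mor: pronoun|she verb|be preposition|on determiner|a noun|stool",
    "*EXA: do you see anything else going on ?",
    "@End")
}

test_that("parsing maps maze coding, tiers and prompts correctly", {
  t <- parse_chat(fixture_doc())
  expect_s3_class(t, "chat_transcript")
  expect_identical(t$participant_id, "P7")
  expect_identical(t$visit_id, "V2")
  expect_equal(t$duration_s, 50.4)
  expect_length(t$cunits, 2L)
  expect_identical(t$prompts, 1L)

  cu1 <- t$cunits[[1]]
  surf <- vapply(cu1$tokens, `[[`, "", "surface")
  expect_identical(surf, c("um", "the", "boy", "the", "girl", "is", "falling"))
  content <- Filter(function(tk) !tk$in_maze && !tk$is_filled_pause, cu1$tokens)
  expect_identical(vapply(content, `[[`, "", "surface"),
                   c("the", "girl", "is", "falling"))
  expect_identical(vapply(content, `[[`, "", "pos"),
                   c("determiner", "noun", "verb", "verb"))
  expect_identical(vapply(content, `[[`, "", "lemma"),
                   c("the", "girl", "be", "fall"))
  kinds <- vapply(cu1$maze_events, `[[`, "", "kind")
  expect_setequal(kinds, c("filled_pause", "revision"))
  expect_true(cu1$tokens[[1]]$is_filled_pause)
  expect_identical(cu1$tokens[[1]]$pos, "nonword")
  expect_true(cu1$tokens[[2]]$in_maze && cu1$tokens[[3]]$in_maze)
  # relation tier: 4 relations, COMP marks an embedding
  expect_length(cu1$relations, 4L)
  expect_identical(sum(vapply(cu1$relations, `[[`, logical(1), "is_embedding")), 1L)
})

test_that("parse errors are informative and name the offending line", {
  expect_error(parse_chat(character(0)), "empty")
  expect_error(parse_chat("@Begin\n@End"), "empty")
  # misaligned %mor: 2 entries for 3 non-maze tokens
  doc <- c("@Duration: 30",
           "*PAR: the boy runs .",
           "%mor: determiner|the noun|boy")
  expect_error(parse_chat(doc), "line 3.*misaligned|misaligned")
  # missing duration
  expect_error(parse_chat(c("*PAR: hello there .")), "@Duration")
  # %gra index out of range
  doc2 <- c("@Duration: 30", "*PAR: boy runs .",
            "%mor: noun|boy verb|run", "%gra: 1|3|SUBJ")
  expect_error(parse_chat(doc2), "out of range")
})

test_that("write_chat is the exact inverse of parse_chat", {
  t <- parse_chat(fixture_doc())
  expect_identical(parse_chat(write_chat(t)), t)
  # property: round trip and maze conservation over generated transcripts
  for (s in c(11, 12, 13, 14, 15)) {
    g <- generate_transcript(random_transcript_plan(s))
    t2 <- parse_chat(write_chat(g$transcript))
    expect_identical(t2, g$transcript)
    n_maze <- function(t) sum(vapply(t$cunits, function(cu)
      sum(vapply(cu$tokens, `[[`, logical(1), "in_maze")), integer(1)))
    expect_identical(n_maze(t2), n_maze(g$transcript))
  }
})

test_that("degenerate transcripts are refused", {
  t <- parse_chat(fixture_doc())
  t$cunits <- list()
  expect_error(write_chat(t), "C-unit")
  expect_error(chat_transcript("P", "V", 0, t["cunits"]), "positive")
})

test_that("percent agreement matches direct arithmetic on simple cases", {
  w <- sprintf("w%02d", 1:10)
  a <- make_simple_transcript(w)
  b <- make_simple_transcript(w)
  expect_equal(percent_agreement(a, b), 100)
  # one substituted token out of ten
  w2 <- w; w2[4] <- "zz"
  b2 <- make_simple_transcript(w2)
  expect_equal(percent_agreement(a, b2), 90)
  # symmetry
  expect_equal(percent_agreement(a, b2), percent_agreement(b2, a))
  # identifiers must agree
  c2 <- make_simple_transcript(w, pid = "OTHER")
  expect_error(percent_agreement(a, c2), "identifiers")
})

test_that("percent agreement equals the brute-force alignment oracle", {
  set.seed(42)
  vocab <- c("the", "boy", "girl", "runs", "falls", "stool", "cookie")
  for (rep in 1:25) {
    na <- sample(4:12, 1); nb <- sample(4:12, 1)
    wa <- sample(vocab, na, replace = TRUE)
    # perturb wa by random ins/del/sub to get wb
    wb <- wa
    for (k in seq_len(sample(0:4, 1))) {
      op <- sample(c("ins", "del", "sub"), 1)
      if (op == "ins") {
        at <- sample(length(wb) + 1L, 1)
        wb <- append(wb, sample(vocab, 1), after = at - 1L)
      } else if (op == "del" && length(wb) > 1L) {
        wb <- wb[-sample(length(wb), 1)]
      } else {
        wb[sample(length(wb), 1)] <- sample(vocab, 1)
      }
    }
    ta <- make_simple_transcript(wa)
    tb <- make_simple_transcript(wb)
    expect_equal(percent_agreement(ta, tb), oracle_agreement(wa, wb))
  }
})

test_that("semantic-coding agreement aligns matched unit codes", {
  lex <- as_content_lexicon(list(boy = "boy", girl = "girl", stool = "stool"))
  a <- make_simple_transcript(c("boy", "girl", "stool"))
  b <- make_simple_transcript(c("boy", "stool"))
  expect_equal(percent_agreement(a, a, level = "semantic_coding", lexicon = lex), 100)
  # codes (boy, girl, stool) vs (boy, stool): one deletion in 3 columns
  expect_equal(percent_agreement(a, b, level = "semantic_coding", lexicon = lex),
               100 * 2 / 3)
})
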