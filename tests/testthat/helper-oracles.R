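# Independent oracles used across the suite. These deliberately take a
# different algorithmic route from the package implementations.

# Top-down memoized edit-distance on prefixes, plus a greedy backward
# reconstruction preferring diagonal (match/substitution) moves, then
# deletion, then insertion -- the stated tie-break. Returns agreement in
# percent, as matches / alignment columns * 100.
oracle_agreement <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  cost <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    v <- min(cost(i - 1L, j - 1L) + (a[i] != b[j]),
             cost(i - 1L, j) + 1L,
             cost(i, j - 1L) + 1L)
    assign(key, v, envir = memo)
    v
  }
  i <- length(a); j <- length(b)
  matches <- 0L; columns <- 0L
  while (i > 0L || j > 0L) {
    columns <- columns + 1L
    if (i > 0L && j > 0L && cost(i, j) == cost(i - 1L, j - 1L) + (a[i] != b[j])) {
      if (a[i] == b[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && cost(i, j) == cost(i - 1L, j) + 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  100 * matches / columns
}

# Spearman rho by the classical rank formula (valid without ties).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Build a count_summary directly (bypassing transcripts) for formula tests.
make_counts <- function(nouns = 0, verbs = 0, pronouns = 0, adjectives = 0,
                        adverbs = 0, prepositions = 0, conjunctions = 0,
                        determiners = 0, total_words, unique_words,
                        n_utterances, filled_pauses = 0, unfilled_pauses = 0,
                        repetitions = 0, revisions = 0, false_starts = 0,
                        embedding_relations = 0, total_relations = 0,
                        matched_content_units = 0, duration_s = 60) {
  structure(list(total_words = total_words, unique_words = unique_words,
                 n_utterances = n_utterances, nouns = nouns, verbs = verbs,
                 pronouns = pronouns, adjectives = adjectives,
                 adverbs = adverbs, prepositions = prepositions,
                 conjunctions = conjunctions, determiners = determiners,
                 filled_pauses = filled_pauses,
                 unfilled_pauses = unfilled_pauses,
                 repetitions = repetitions, revisions = revisions,
                 false_starts = false_starts,
                 embedding_relations = embedding_relations,
                 total_relations = total_relations,
                 matched_content_units = matched_content_units,
                 duration_s = duration_s),
            class = "count_summary")
}

# Minimal single-C-unit transcript built from plain word/POS vectors.
make_simple_transcript <- function(words, pos = rep("noun", length(words)),
                                   duration_s = 60, pid = "P1", vid = "V1") {
  toks <- mapply(function(w, p) chat_token(w, pos = p), words, pos,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  chat_transcript(pid, vid, duration_s, list(cunit(toks)))
}
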