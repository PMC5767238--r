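# Discourse-measure layer: raw counts over a parsed transcript, semantic
# content-unit matching, and the derived measure set.
#
# Counting conventions (all deliberate and documented):
#   * total_words counts non-maze, non-filled-pause, non-nonword tokens;
#     maze-internal material is disfluency, not content.
#   * unique_words counts distinct lower-cased surfaces among those.
#   * examiner prompts never contribute tokens; their time is inside
#     duration_s.
#   * undefined ratios (zero denominators) are NA, never 0.

#' Tally raw counts for one transcript
#'
#' Computes the count layer beneath every discourse measure: word and
#' per-POS counts over non-maze material, maze-event counts by kind,
#' grammatical-relation counts, matched content units and duration.
#'
#' @param t A valid \code{\link{chat_transcript}}.
#' @param lexicon A \code{content_lexicon}; defaults to the built-in
#'   Cookie Theft checklist.
#' @return A \code{count_summary} list.
#' @export
tally_counts <- function(t, lexicon = default_content_lexicon()) {
  validate_transcript(t)
  if (length(lexicon) == 0L) stop("content lexicon is empty")
  all_content <- unlist(lapply(t$cunits, content_tokens), recursive = FALSE)
  words <- Filter(function(tk) tk$pos != "nonword", all_content)
  if (length(words) == 0L)
    stop("empty sample: transcript has no non-maze words")
  surfaces <- vapply(words, `[[`, "", "surface")
  pos <- vapply(words, `[[`, "", "pos")
  pos_count <- function(p) sum(pos == p)

  maze_kind <- unlist(lapply(t$cunits, function(cu)
    vapply(cu$maze_events, `[[`, "", "kind")))
  maze_count <- function(k) sum(maze_kind == k)

  rels <- unlist(lapply(t$cunits, `[[`, "relations"), recursive = FALSE)
  matched <- match_semantic_units(t, lexicon)

  structure(list(
    total_words = length(words),
    unique_words = length(unique(surfaces)),
    n_utterances = length(t$cunits),
    nouns = pos_count("noun"), verbs = pos_count("verb"),
    pronouns = pos_count("pronoun"), adjectives = pos_count("adjective"),
    adverbs = pos_count("adverb"), prepositions = pos_count("preposition"),
    conjunctions = pos_count("conjunction"),
    determiners = pos_count("determiner"),
    filled_pauses = maze_count("filled_pause"),
    unfilled_pauses = maze_count("unfilled_pause"),
    repetitions = maze_count("repetition"),
    revisions = maze_count("revision"),
    false_starts = maze_count("false_start"),
    embedding_relations = sum(vapply(rels, `[[`, logical(1), "is_embedding")),
    total_relations = length(rels),
    matched_content_units = length(matched),
    duration_s = t$duration_s
  ), class = "count_summary")
}

#' Match content units against a transcript
#'
#' A unit is matched if any of its trigger patterns occurs contiguously in
#' the non-maze lemma sequence of some C-unit; each unit counts at most
#' once regardless of repetition. Multi-word patterns may not span C-unit
#' boundaries.
#'
#' @inheritParams tally_counts
#' @return Character vector of matched unit identifiers, in order of
#'   first mention.
#' @export
match_semantic_units <- function(t, lexicon = default_content_lexicon()) {
  lemma_seqs <- lapply(t$cunits, function(cu) {
    ct <- Filter(function(tk) tk$pos != "nonword", content_tokens(cu))
    vapply(ct, `[[`, "", "lemma")
  })
  matched <- character(0)
  for (lem in lemma_seqs) {
    if (!length(lem)) next
    for (unit in names(lexicon)) {
      if (unit %in% matched) next
      for (pat in lexicon[[unit]]) {
        if (pattern_in_sequence(strsplit(pat, " ", fixed = TRUE)[[1]], lem)) {
          matched <- c(matched, unit)
          break
        }
      }
    }
  }
  matched
}

pattern_in_sequence <- function(pat, lem) {
  k <- length(pat); n <- length(lem)
  if (k == 0L || k > n) return(FALSE)
  for (s in seq_len(n - k + 1L))
    if (all(lem[s:(s + k - 1L)] == pat)) return(TRUE)
  FALSE
}

#' Derive the discourse measure set from raw counts
#'
#' Produces the ten factor-forming measures (semantic: percent nouns,
#' percent verbs, pronoun index; syntax: verb index, proposition density,
#' grammatical complexity; lexical: type-token ratio, unique words,
#' semantic-unit count; fluency: maze index) and the five descriptive
#' measures (total words, total semantic units, MLU, words per minute,
#' semantic units per minute).
#'
#' Formulas:
#' \itemize{
#'   \item pronoun_index = pronouns / (nouns + pronouns)
#'   \item verb_index = verbs / n_utterances
#'   \item proposition_density = (verbs + adjectives + adverbs +
#'     prepositions + conjunctions) / total_words
#'   \item grammatical_complexity = embedding_relations / total_relations
#'   \item type_token_ratio = unique_words / total_words
#'   \item maze_index = (filled_pauses + false_starts + revisions +
#'     repetitions) / n_utterances; set
#'     \code{include_unfilled_pauses = TRUE} to also count unfilled
#'     pauses in the numerator
#'   \item percent_nouns = 100 * nouns / total_words; percent_verbs
#'     likewise
#'   \item mlu = total_words / n_utterances; words_per_minute =
#'     60 * total_words / duration_s; semantic_units_per_minute =
#'     60 * matched_content_units / duration_s
#' }
#' Zero-denominator ratios are returned as \code{NA} (flagged missing),
#' never as 0.
#'
#' @param c A \code{count_summary} from \code{\link{tally_counts}}.
#' @param include_unfilled_pauses Count unfilled pauses in the maze-index
#'   numerator? Default \code{FALSE} (the index counts filled pauses,
#'   false starts, revisions and repetitions).
#' @return A \code{feature_vector} (named list).
#' @export
derive_features <- function(c, include_unfilled_pauses = FALSE) {
  stopifnot(inherits(c, "count_summary"))
  if (c$total_words <= 0L) stop("derive_features needs total_words > 0")
  if (c$n_utterances <= 0L) stop("derive_features needs n_utterances > 0")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  maze_num <- c$filled_pauses + c$false_starts + c$revisions + c$repetitions +
    if (include_unfilled_pauses) c$unfilled_pauses else 0L
  structure(list(
    percent_nouns = 100 * c$nouns / c$total_words,
    percent_verbs = 100 * c$verbs / c$total_words,
    pronoun_index = ratio(c$pronouns, c$nouns + c$pronouns),
    verb_index = c$verbs / c$n_utterances,
    proposition_density = (c$verbs + c$adjectives + c$adverbs +
                             c$prepositions + c$conjunctions) / c$total_words,
    grammatical_complexity = ratio(c$embedding_relations, c$total_relations),
    type_token_ratio = c$unique_words / c$total_words,
    unique_words = c$unique_words,
    semantic_unit_count = c$matched_content_units,
    maze_index = maze_num / c$n_utterances,
    total_words = c$total_words,
    total_semantic_units = c$matched_content_units,
    mlu = c$total_words / c$n_utterances,
    words_per_minute = 60 * c$total_words / c$duration_s,
    semantic_units_per_minute = 60 * c$matched_content_units / c$duration_s
  ), class = "feature_vector")
}

#' Extract the full feature vector from a transcript
#'
#' Convenience composition of \code{\link{tally_counts}} and
#' \code{\link{derive_features}}.
#'
#' @inheritParams tally_counts
#' @inheritParams derive_features
#' @return A \code{feature_vector}.
#' @export
extract_features <- function(t, lexicon = default_content_lexicon(),
                             include_unfilled_pauses = FALSE) {
  derive_features(tally_counts(t, lexicon), include_unfilled_pauses)
}

feature_names <- function() {
  c("percent_nouns", "percent_verbs", "pronoun_index", "verb_index",
    "proposition_density", "grammatical_complexity", "type_token_ratio",
    "unique_words", "semantic_unit_count", "maze_index", "total_words",
    "total_semantic_units", "mlu", "words_per_minute",
    "semantic_units_per_minute")
}

#' Write a feature table to CSV
#'
#' One row per (participant, visit); missing values are written as empty
#' fields. Column order is fixed: identifiers first, then the measures in
#' the order of \code{\link{derive_features}}'s documentation.
#'
#' @param features Named list of \code{feature_vector}s, or a list of
#'   lists with elements \code{participant_id}, \code{visit_id},
#'   \code{features}.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_feature_table <- function(features, path) {
  rows <- lapply(features, function(x) {
    fv <- if (inherits(x, "feature_vector")) x else x$features
    pid <- if (inherits(x, "feature_vector")) NA_character_ else x$participant_id
    vid <- if (inherits(x, "feature_vector")) NA_character_ else x$visit_id
    cbind(data.frame(participant_id = pid, visit_id = vid,
                     stringsAsFactors = FALSE),
          as.data.frame(unclass(fv)[feature_names()]))
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}
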