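# Domain types for the supported CHAT dialect: tokens, maze events,
# grammatical relations, C-units and transcripts. All constructors validate
# their invariants eagerly so that downstream counting can assume clean input.

#' Closed part-of-speech vocabulary
#'
#' Every token carries exactly one tag from this closed set. Open-class
#' content tags (noun, verb, adjective, adverb) and closed-class tags
#' (pronoun, preposition, conjunction, determiner) drive the discourse
#' measures; \code{"nonword"} marks filled pauses and other non-lexical
#' vocalisations, and \code{"other"} everything else (including material
#' inside mazes, which is never tagged from the morphology tier).
#'
#' @return Character vector of the ten POS tags.
#' @export
pos_vocabulary <- function() {
  c("noun", "verb", "pronoun", "adjective", "adverb",
    "preposition", "conjunction", "determiner", "other", "nonword")
}

# Grammatical-relation labels treated as marking a syntactic embedding
# (clausal subjects/complements/modifiers), in the spirit of dependency
# grammars used for automated language-sample analysis.
EMBEDDING_RELATIONS <- c("CSUBJ", "COMP", "XCOMP", "CMOD", "XMOD",
                         "CJCT", "XJCT", "CPRED", "CPOBJ", "COBJ")

MAZE_KINDS <- c("filled_pause", "unfilled_pause", "repetition",
                "revision", "false_start")

#' Construct a token
#'
#' @param surface Lower-cased word form (non-empty).
#' @param lemma Base form; defaults to the surface.
#' @param pos One tag from \code{\link{pos_vocabulary}}.
#' @param in_maze Does the token lie inside retraced/repeated material?
#' @param is_filled_pause Is it a filler ("um", "uh")? Implies
#'   \code{pos = "nonword"}.
#' @return A \code{chat_token} object.
#' @export
chat_token <- function(surface, lemma = surface, pos = "other",
                       in_maze = FALSE, is_filled_pause = FALSE) {
  surface <- tolower(as.character(surface))
  if (!nzchar(surface)) stop("token surface must be non-empty")
  if (!(pos %in% pos_vocabulary()))
    stop("unknown POS tag: ", pos)
  if (is_filled_pause && pos != "nonword")
    stop("filled-pause tokens must have POS 'nonword'")
  structure(list(surface = surface, lemma = tolower(as.character(lemma)),
                 pos = pos, in_maze = isTRUE(in_maze),
                 is_filled_pause = isTRUE(is_filled_pause)),
            class = "chat_token")
}

#' Construct a maze event
#'
#' A maze is disfluent material excluded from content counting: filled and
#' unfilled pauses, repetitions, revisions and false starts. For kinds that
#' cover tokens, \code{token_span} records which token positions of the
#' containing C-unit lie inside the maze; unfilled pauses cover no tokens
#' and instead record the token index after which the pause occurred
#' (\code{after_token}, 0 = utterance-initial).
#'
#' @param kind One of \code{"filled_pause"}, \code{"unfilled_pause"},
#'   \code{"repetition"}, \code{"revision"}, \code{"false_start"}.
#' @param cunit_index Ordinal of the containing C-unit.
#' @param token_span Integer vector of covered token positions.
#' @param after_token Position marker for unfilled pauses.
#' @return A \code{maze_event} object.
#' @export
maze_event <- function(kind, cunit_index = NA_integer_,
                       token_span = integer(0), after_token = NA_integer_) {
  if (!(kind %in% MAZE_KINDS)) stop("unknown maze kind: ", kind)
  if (kind == "unfilled_pause" && length(token_span))
    stop("unfilled pauses cover no tokens")
  structure(list(kind = kind, cunit_index = as.integer(cunit_index),
                 token_span = as.integer(token_span),
                 after_token = as.integer(after_token)),
            class = "maze_event")
}

#' Construct a grammatical relation
#'
#' Indices refer to positions in the C-unit's non-maze, non-filled-pause
#' token sequence (the same index space as the morphology tier).
#'
#' @param label Relation name (upper-cased).
#' @param head_index,dependent_index Token ordinals; must differ.
#'   \code{head_index = 0} denotes the virtual root (ROOT relations).
#' @param is_embedding Marks a syntactic embedding; defaults to membership
#'   of \code{label} in the built-in embedding label set.
#' @return A \code{gram_relation} object.
#' @export
gram_relation <- function(label, head_index, dependent_index,
                          is_embedding = toupper(label) %in% EMBEDDING_RELATIONS) {
  head_index <- as.integer(head_index)
  dependent_index <- as.integer(dependent_index)
  if (head_index == dependent_index)
    stop("a relation's head and dependent must differ")
  if (dependent_index < 1L || head_index < 0L)
    stop("relation indices must be positive (head 0 = virtual root)")
  structure(list(label = toupper(label), head_index = head_index,
                 dependent_index = dependent_index,
                 is_embedding = isTRUE(is_embedding)),
            class = "gram_relation")
}

#' Construct a C-unit
#'
#' A C-unit (communication unit) is an independent clause plus all of its
#' modifiers -- the utterance unit for segmentation and all per-utterance
#' denominators. A valid C-unit contains at least one non-maze,
#' non-filled-pause token or at least one maze event.
#'
#' @param tokens List of \code{\link{chat_token}}s, in spoken order
#'   (including maze-internal tokens at their positions).
#' @param relations List of \code{\link{gram_relation}}s.
#' @param maze_events List of \code{\link{maze_event}}s.
#' @param terminator Utterance terminator, one of \code{". ? !"}.
#' @return A \code{cunit} object.
#' @export
cunit <- function(tokens, relations = list(), maze_events = list(),
                  terminator = ".") {
  if (!(terminator %in% c(".", "?", "!")))
    stop("terminator must be one of . ? !")
  content <- vapply(tokens, function(tk) !tk$in_maze && !tk$is_filled_pause,
                    logical(1))
  if (!any(content) && length(maze_events) == 0L)
    stop("a C-unit needs a content token or a maze event")
  n_content <- sum(content)
  for (r in relations) {
    if (r$head_index > n_content || r$dependent_index > n_content ||
        r$head_index < 0L || r$dependent_index < 1L)
      stop("relation indices must reference non-maze token positions")
  }
  structure(list(tokens = tokens, relations = relations,
                 maze_events = maze_events, terminator = terminator),
            class = "cunit")
}

#' Construct a transcript
#'
#' @param participant_id,visit_id Opaque identifier strings.
#' @param duration_s Sample duration in seconds (> 0), including any
#'   scripted examiner prompts.
#' @param cunits Non-empty list of \code{\link{cunit}}s.
#' @param prompts Count of scripted examiner prompts (excluded from all
#'   content measures; their time is part of \code{duration_s}).
#' @return A \code{chat_transcript} object.
#' @export
chat_transcript <- function(participant_id, visit_id, duration_s, cunits,
                            prompts = 0L) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      is.na(duration_s) || duration_s <= 0)
    stop("duration_s must be a single positive number")
  if (length(cunits) == 0L)
    stop("a transcript must contain at least one C-unit")
  structure(list(participant_id = as.character(participant_id),
                 visit_id = as.character(visit_id),
                 duration_s = as.numeric(duration_s),
                 cunits = cunits, prompts = as.integer(prompts)),
            class = "chat_transcript")
}

#' @export
print.chat_transcript <- function(x, ...) {
  n_tok <- sum(vapply(x$cunits, function(cu) length(cu$tokens), integer(1)))
  cat(sprintf(
    "<chat_transcript> participant %s, visit %s: %d C-units, %d tokens, %.1f s\n",
    x$participant_id, x$visit_id, length(x$cunits), n_tok, x$duration_s))
  invisible(x)
}

# Content tokens = non-maze, non-filled-pause tokens of a C-unit; the index
# space shared by the %mor and %gra tiers.
content_tokens <- function(cu) {
  Filter(function(tk) !tk$in_maze && !tk$is_filled_pause, cu$tokens)
}

#' Validate a transcript against all type invariants
#'
#' Checks every C-unit, token, relation and maze event; errors with an
#' informative message on the first violation.
#'
#' @param t A \code{chat_transcript}.
#' @return \code{t}, invisibly.
#' @export
validate_transcript <- function(t) {
  stopifnot(inherits(t, "chat_transcript"))
  if (t$duration_s <= 0) stop("duration_s must be > 0")
  if (length(t$cunits) == 0L) stop("transcript has no C-units")
  for (i in seq_along(t$cunits)) {
    cu <- t$cunits[[i]]
    for (tk in cu$tokens) {
      if (!nzchar(tk$surface)) stop("empty token surface in C-unit ", i)
      if (!(tk$pos %in% pos_vocabulary()))
        stop("invalid POS in C-unit ", i)
      if (tk$is_filled_pause && tk$pos != "nonword")
        stop("filled pause with non-nonword POS in C-unit ", i)
    }
    n_content <- length(content_tokens(cu))
    for (r in cu$relations) {
      if (r$head_index == r$dependent_index)
        stop("self-relation in C-unit ", i)
      if (r$head_index > n_content || r$dependent_index > n_content ||
          r$head_index < 0L || r$dependent_index < 1L)
        stop("relation index out of range in C-unit ", i)
    }
    for (ev in cu$maze_events) {
      if (!(ev$kind %in% MAZE_KINDS)) stop("invalid maze kind in C-unit ", i)
      if (length(ev$token_span) &&
          (min(ev$token_span) < 1L || max(ev$token_span) > length(cu$tokens)))
        stop("maze span out of range in C-unit ", i)
    }
    if (length(content_tokens(cu)) == 0L && length(cu$maze_events) == 0L)
      stop("C-unit ", i, " has neither content tokens nor maze events")
  }
  invisible(t)
}
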