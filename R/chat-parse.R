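# Parser for the supported CHAT dialect.
#
# Supported lines:
#   @Begin / @End                      file delimiters (optional)
#   @Participants: PAR Participant, EXA Examiner
#   @ID: PAR|<participant_id>|<visit_id>
#   @Duration: <seconds>               required sample duration
#   *PAR: <main line>                  one C-unit per line
#   %mor: pos|lemma ...                one entry per non-maze content token
#   %gra: dep|head|LABEL ...           one entry per grammatical relation
#   *EXA: ...                          examiner prompt (counted, not parsed)
#
# Main-line maze coding:
#   &-um            filled pause (nonword token + maze event)
#   (.)             unfilled pause (maze event, no token)
#   <w1 w2> [/]     repetition   (tokens in maze)
#   <w1 w2> [//]    revision
#   <w1 w2> [/-]    false start
#   w [/]           single-token retrace shorthand
# The line ends with a terminator: . ? !

#' Parse a CHAT-dialect document into a transcript
#'
#' Each participant main line becomes one C-unit. Maze markers are mapped
#' to \code{in_maze} flags and \code{\link{maze_event}} records; POS tags
#' and lemmas come from the \verb{%mor} tier when present, otherwise from
#' \code{tagger}. Examiner-tier utterances contribute to the prompt count
#' only.
#'
#' @param text Character vector of lines, or a single string with
#'   embedded newlines.
#' @param tagger Fallback tagger: \code{function(surfaces)} returning a
#'   data.frame with columns \code{pos} and \code{lemma}, used for C-units
#'   lacking a \verb{%mor} tier. Defaults to
#'   \code{\link{default_tagger}}.
#' @return A validated \code{\link{chat_transcript}}.
#' @seealso \code{\link{write_chat}} for the inverse operation,
#'   \code{\link{read_chat}} to parse a file.
#' @export
parse_chat <- function(text, tagger = default_tagger) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(text)
  if (!length(lines) || all(!nzchar(lines)))
    stop("empty CHAT document")

  participant_code <- "PAR"
  participant_id <- "P1"; visit_id <- "V1"
  duration_s <- NA_real_
  prompts <- 0L
  cunits <- list()
  pending <- NULL  # last participant C-unit awaiting tier lines

  finish_pending <- function(p) {
    if (is.null(p)) return(NULL)
    if (!p$mor_seen) {
      # pluggable fallback tagger fills POS/lemma for content tokens
      idx <- which(vapply(p$tokens, function(tk)
        !tk$in_maze && !tk$is_filled_pause, logical(1)))
      if (length(idx)) {
        tags <- tagger(vapply(p$tokens[idx], `[[`, "", "surface"))
        for (k in seq_along(idx)) {
          p$tokens[[idx[k]]]$pos <- tags$pos[k]
          p$tokens[[idx[k]]]$lemma <- tags$lemma[k]
        }
      }
    }
    cunit(p$tokens, p$relations, p$maze_events, p$terminator)
  }

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) next
    if (startsWith(line, "@")) {
      if (grepl("^@Participants:", line)) {
        first <- trimws(strsplit(sub("^@Participants:", "", line), ",")[[1]][1])
        participant_code <- strsplit(first, "\\s+")[[1]][1]
      } else if (grepl("^@ID:", line)) {
        parts <- strsplit(trimws(sub("^@ID:", "", line)), "|", fixed = TRUE)[[1]]
        if (length(parts) >= 3L) {
          participant_id <- parts[2]; visit_id <- parts[3]
        }
      } else if (grepl("^@Duration:", line)) {
        duration_s <- suppressWarnings(as.numeric(trimws(sub("^@Duration:", "", line))))
      }
      next
    }
    if (startsWith(line, "*")) {
      speaker <- sub("^\\*([^:]+):.*$", "\\1", line)
      body <- trimws(sub("^\\*[^:]+:", "", line))
      if (speaker != participant_code) {
        prompts <- prompts + 1L
        next
      }
      if (!is.null(pending)) cunits[[length(cunits) + 1L]] <- finish_pending(pending)
      pending <- parse_main_line(body, ln)
      next
    }
    if (startsWith(line, "%mor:")) {
      if (is.null(pending)) stop("line ", ln, ": %mor tier without a main line")
      pending <- apply_mor_tier(pending, trimws(sub("^%mor:", "", line)), ln)
      next
    }
    if (startsWith(line, "%gra:")) {
      if (is.null(pending)) stop("line ", ln, ": %gra tier without a main line")
      pending <- apply_gra_tier(pending, trimws(sub("^%gra:", "", line)), ln)
      next
    }
    # any other tier (%com, %err, ...) is recorded but unused
  }
  if (!is.null(pending)) cunits[[length(cunits) + 1L]] <- finish_pending(pending)

  if (length(cunits) == 0L)
    stop("empty CHAT document: no participant utterances found")
  if (is.na(duration_s))
    stop("missing @Duration header: sample duration is required")

  validate_transcript(chat_transcript(participant_id, visit_id, duration_s,
                                      cunits, prompts))
}

# Parse one participant main line into a provisional C-unit structure.
parse_main_line <- function(body, line_no) {
  fields <- strsplit(body, "\\s+")[[1]]
  fields <- fields[nzchar(fields)]
  if (!length(fields)) stop("line ", line_no, ": empty main line")
  terminator <- "."
  if (fields[length(fields)] %in% c(".", "?", "!")) {
    terminator <- fields[length(fields)]
    fields <- fields[-length(fields)]
  }
  tokens <- list(); maze_events <- list()
  group_start <- NA_integer_; in_group <- FALSE
  i <- 1L
  while (i <= length(fields)) {
    f <- fields[i]
    if (f == "(.)") {
      maze_events[[length(maze_events) + 1L]] <-
        maze_event("unfilled_pause", after_token = length(tokens))
    } else if (startsWith(f, "&-")) {
      w <- substring(f, 3L)
      if (!nzchar(w)) stop("line ", line_no, ": empty filler '&-'")
      tokens[[length(tokens) + 1L]] <-
        chat_token(w, pos = "nonword", is_filled_pause = TRUE)
      maze_events[[length(maze_events) + 1L]] <-
        maze_event("filled_pause", token_span = length(tokens))
    } else if (startsWith(f, "<")) {
      in_group <- TRUE
      group_start <- length(tokens) + 1L
      w <- sub("^<", "", f)
      closed <- endsWith(w, ">")
      if (closed) w <- sub(">$", "", w)
      if (nzchar(w))
        tokens[[length(tokens) + 1L]] <- chat_token(w, pos = "other", in_maze = TRUE)
      if (closed) in_group <- FALSE  # kind assigned when the marker arrives
    } else if (in_group) {
      closed <- endsWith(f, ">")
      w <- if (closed) sub(">$", "", f) else f
      if (nzchar(w))
        tokens[[length(tokens) + 1L]] <- chat_token(w, pos = "other", in_maze = TRUE)
      if (closed) in_group <- FALSE
    } else if (f %in% c("[/]", "[//]", "[/-]")) {
      kind <- switch(f, "[/]" = "repetition", "[//]" = "revision",
                     "[/-]" = "false_start")
      if (is.na(group_start) || group_start > length(tokens)) {
        # single-token shorthand: the preceding bare token is the retrace
        if (!length(tokens)) stop("line ", line_no, ": retrace marker ", f,
                                  " with no preceding material")
        group_start <- length(tokens)
        tokens[[group_start]]$in_maze <- TRUE
      }
      maze_events[[length(maze_events) + 1L]] <-
        maze_event(kind, token_span = seq.int(group_start, length(tokens)))
      group_start <- NA_integer_
    } else {
      tokens[[length(tokens) + 1L]] <- chat_token(f, pos = "other")
      group_start <- NA_integer_
    }
    i <- i + 1L
  }
  if (in_group) stop("line ", line_no, ": unclosed '<' retrace group")
  list(tokens = tokens, relations = list(), maze_events = maze_events,
       terminator = terminator, mor_seen = FALSE, line_no = line_no)
}

apply_mor_tier <- function(pending, body, line_no) {
  entries <- strsplit(body, "\\s+")[[1]]
  entries <- entries[nzchar(entries)]
  idx <- which(vapply(pending$tokens, function(tk)
    !tk$in_maze && !tk$is_filled_pause, logical(1)))
  if (length(entries) != length(idx))
    stop("line ", line_no, ": %mor has ", length(entries),
         " entries but the main line has ", length(idx),
         " non-maze tokens (misaligned tiers)")
  for (k in seq_along(entries)) {
    parts <- strsplit(entries[k], "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("line ", line_no, ": malformed %mor entry '", entries[k], "'")
    if (!(parts[1] %in% pos_vocabulary()))
      stop("line ", line_no, ": unknown POS '", parts[1], "' in %mor tier")
    pending$tokens[[idx[k]]]$pos <- parts[1]
    pending$tokens[[idx[k]]]$lemma <- tolower(parts[2])
  }
  pending$mor_seen <- TRUE
  pending
}

apply_gra_tier <- function(pending, body, line_no) {
  entries <- strsplit(body, "\\s+")[[1]]
  entries <- entries[nzchar(entries)]
  n_content <- sum(vapply(pending$tokens, function(tk)
    !tk$in_maze && !tk$is_filled_pause, logical(1)))
  rels <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    parts <- strsplit(entries[k], "|", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("line ", line_no, ": malformed %gra entry '", entries[k], "'")
    dep <- suppressWarnings(as.integer(parts[1]))
    head_i <- suppressWarnings(as.integer(parts[2]))
    if (is.na(dep) || is.na(head_i))
      stop("line ", line_no, ": non-numeric %gra indices in '", entries[k], "'")
    if (dep > n_content || head_i > n_content || dep < 1L || head_i < 0L)
      stop("line ", line_no, ": %gra index out of range in '", entries[k], "'")
    rels[[k]] <- gram_relation(parts[3], head_i, dep)
  }
  pending$relations <- rels
  pending
}

#' Read and parse a CHAT file
#'
#' @param path Path to a UTF-8 \code{.cha} file in the supported dialect.
#' @inheritParams parse_chat
#' @return A \code{\link{chat_transcript}}.
#' @export
read_chat <- function(path, tagger = default_tagger) {
  parse_chat(readLines(path, encoding = "UTF-8", warn = FALSE), tagger = tagger)
}

#' Minimal closed-class fallback tagger
#'
#' Used when a C-unit has no \verb{%mor} tier. Looks surfaces up in small
#' closed-class lists (pronouns, determiners, prepositions, conjunctions,
#' auxiliaries, common adverbs); everything else is tagged \code{noun}.
#' The lemma is the surface form. This is deliberately crude -- gold tags
#' should come from the morphology tier.
#'
#' @param surfaces Character vector of lower-cased word forms.
#' @return data.frame with columns \code{pos}, \code{lemma}.
#' @export
default_tagger <- function(surfaces) {
  closed <- list(
    pronoun = c("i", "you", "he", "she", "it", "we", "they", "me", "him",
                "her", "us", "them", "his", "hers", "its", "their", "this",
                "that", "these", "those", "something", "someone"),
    determiner = c("the", "a", "an", "some", "any", "each", "every", "no"),
    preposition = c("in", "on", "at", "of", "to", "from", "with", "by",
                    "for", "over", "under", "into", "out", "off", "about"),
    conjunction = c("and", "or", "but", "because", "while", "so", "if",
                    "when", "although", "that"),
    verb = c("is", "are", "was", "were", "be", "been", "being", "am",
             "has", "have", "had", "do", "does", "did", "will", "would",
             "can", "could", "may", "might", "shall", "should", "must",
             "going", "getting", "falling", "running", "standing",
             "washing", "drying", "reaching", "taking", "overflowing"),
    adverb = c("very", "here", "there", "not", "also", "just", "too",
               "then", "now", "away", "down", "up")
  )
  pos <- rep("noun", length(surfaces))
  for (tag in names(closed)) pos[surfaces %in% closed[[tag]]] <- tag
  data.frame(pos = pos, lemma = surfaces, stringsAsFactors = FALSE)
}
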