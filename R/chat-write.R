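# Writer for the supported CHAT dialect. write_chat is the exact inverse
# of parse_chat on valid transcripts: parse_chat(write_chat(t)) == t.

#' Serialise a transcript to a CHAT-dialect document
#'
#' Emits the header block, one main line per C-unit with canonical maze
#' markers (\code{&-w}, \code{(.)}, \code{<...> [/]}, \code{[//]},
#' \code{[/-]}), a \verb{%mor} tier for every C-unit with content tokens
#' and a \verb{%gra} tier where relations are present. Round-trip
#' identity with \code{\link{parse_chat}} holds for every valid
#' transcript.
#'
#' @param t A valid \code{\link{chat_transcript}} with at least one
#'   C-unit.
#' @return Character vector of document lines.
#' @export
write_chat <- function(t) {
  validate_transcript(t)
  if (length(t$cunits) == 0L) stop("refusing to write a transcript with zero C-units")
  out <- c("@Begin",
           "@Participants: PAR Participant, EXA Examiner",
           sprintf("@ID: PAR|%s|%s", t$participant_id, t$visit_id),
           sprintf("@Duration: %s", format(t$duration_s, scientific = FALSE)))
  for (cu in t$cunits) {
    out <- c(out, format_main_line(cu))
    ct <- content_tokens(cu)
    if (length(ct)) {
      mor <- vapply(ct, function(tk) paste0(tk$pos, "|", tk$lemma), "")
      out <- c(out, paste0("%mor: ", paste(mor, collapse = " ")))
    }
    if (length(cu$relations)) {
      gra <- vapply(cu$relations, function(r)
        paste0(r$dependent_index, "|", r$head_index, "|", r$label), "")
      out <- c(out, paste0("%gra: ", paste(gra, collapse = " ")))
    }
  }
  # examiner prompts are represented by their count only; re-emit the
  # scripted prompt line so the count survives a round trip
  if (t$prompts > 0L)
    out <- c(out, rep("*EXA: do you see anything else going on ?", t$prompts))
  c(out, "@End")
}

format_main_line <- function(cu) {
  # map each token index to the maze event (if any) whose span starts there
  span_events <- Filter(function(ev)
    ev$kind %in% c("repetition", "revision", "false_start"), cu$maze_events)
  starts <- vapply(span_events, function(ev) ev$token_span[1], integer(1))
  pauses_after <- vapply(
    Filter(function(ev) ev$kind == "unfilled_pause", cu$maze_events),
    `[[`, integer(1), "after_token")
  marker <- c(repetition = "[/]", revision = "[//]", false_start = "[/-]")

  pieces <- character(0)
  if (any(pauses_after == 0L)) pieces <- rep("(.)", sum(pauses_after == 0L))
  i <- 1L
  n <- length(cu$tokens)
  while (i <= n) {
    hit <- which(starts == i)
    if (length(hit)) {
      ev <- span_events[[hit[1]]]
      grp <- vapply(cu$tokens[ev$token_span], `[[`, "", "surface")
      pieces <- c(pieces,
                  paste0("<", paste(grp, collapse = " "), ">"),
                  marker[[ev$kind]])
      i_end <- max(ev$token_span)
      for (j in seq.int(i, i_end))
        if (any(pauses_after == j)) pieces <- c(pieces, rep("(.)", sum(pauses_after == j)))
      i <- i_end + 1L
      next
    }
    tk <- cu$tokens[[i]]
    pieces <- c(pieces, if (tk$is_filled_pause) paste0("&-", tk$surface) else tk$surface)
    if (any(pauses_after == i)) pieces <- c(pieces, rep("(.)", sum(pauses_after == i)))
    i <- i + 1L
  }
  paste0("*PAR: ", paste(c(pieces, cu$terminator), collapse = " "))
}

#' Write a transcript to a CHAT file
#'
#' @param t A valid \code{\link{chat_transcript}}.
#' @param path Output path (UTF-8).
#' @return \code{path}, invisibly.
#' @export
write_chat_file <- function(t, path) {
  writeLines(write_chat(t), path, useBytes = FALSE)
  invisible(path)
}
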