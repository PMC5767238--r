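# Inter-rater percent agreement between two transcripts of the same
# sample, computed over a global minimum-edit-distance alignment with unit
# costs (insertion = deletion = substitution = 1), ties broken toward
# substitution. Agreement = 100 * matched columns / alignment length.

#' Percent agreement between two transcriptions of one sample
#'
#' Globally aligns the two sequences -- token surfaces for
#' \code{level = "transcription"}, matched semantic-unit codes (in order
#' of first mention) for \code{level = "semantic_coding"} -- by minimum
#' edit distance and reports the percentage of alignment columns that
#' match.
#'
#' @param a,b \code{\link{chat_transcript}}s of the same participant and
#'   visit.
#' @param level \code{"transcription"} (token-level) or
#'   \code{"semantic_coding"} (content-unit codes).
#' @param lexicon Content-unit lexicon used for
#'   \code{level = "semantic_coding"}; defaults to the built-in checklist.
#' @return Percentage in [0, 100]. 100 iff the aligned sequences are
#'   identical.
#' @export
percent_agreement <- function(a, b, level = c("transcription", "semantic_coding"),
                              lexicon = default_content_lexicon()) {
  level <- match.arg(level)
  stopifnot(inherits(a, "chat_transcript"), inherits(b, "chat_transcript"))
  if (a$participant_id != b$participant_id || a$visit_id != b$visit_id)
    stop("transcripts compare different samples: participant/visit identifiers differ")
  seq_of <- function(t) {
    if (level == "transcription") {
      unlist(lapply(t$cunits, function(cu)
        vapply(cu$tokens, `[[`, "", "surface")), use.names = FALSE)
    } else {
      match_semantic_units(t, lexicon)
    }
  }
  sa <- seq_of(a); sb <- seq_of(b)
  if (!length(sa) || !length(sb))
    stop("cannot compute agreement for an empty sequence")
  st <- align_global(sa, sb)
  unname(100 * st["matches"] / st["columns"])
}

# Needleman-Wunsch with unit costs. Returns the number of matched columns
# and the total alignment length of the backtraced optimal alignment.
# Tie-break order during backtrace: diagonal (match/substitution) first,
# then deletion from `a`, then insertion from `b`.
align_global <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    sub_cost <- ifelse(a[i] == b, 0L, 1L)
    row_prev <- D[i, ]
    row <- integer(m + 1L)
    row[1L] <- i
    for (j in seq_len(m)) {
      row[j + 1L] <- min(row_prev[j] + sub_cost[j],  # diag
                         row_prev[j + 1L] + 1L,      # delete a[i]
                         row[j] + 1L)                # insert b[j]
    }
    D[i + 1L, ] <- row
  }
  i <- n; j <- m; matches <- 0L; columns <- 0L
  while (i > 0L || j > 0L) {
    columns <- columns + 1L
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (a[i] != b[j])) {
      if (a[i] == b[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  c(matches = matches, columns = columns)
}
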