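# Content-unit lexicons: named lists mapping a unit identifier to a
# character vector of trigger patterns (space-separated lemma sequences).

#' Read a content-unit lexicon
#'
#' Lexicons are YAML or JSON documents mapping unit identifiers to trigger
#' patterns. A pattern with embedded spaces matches a contiguous lemma
#' sequence.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return Named list of character vectors, classed
#'   \code{content_lexicon}.
#' @export
read_content_lexicon <- function(path) {
  lex <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_content_lexicon(lex)
}

#' Coerce a named list to a content-unit lexicon
#'
#' @param x Named list (or named character vector) of trigger patterns.
#' @return A \code{content_lexicon} object.
#' @export
as_content_lexicon <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("a content lexicon needs a name for every unit")
  lex <- lapply(x, function(p) tolower(as.character(p)))
  if (any(vapply(lex, length, integer(1)) == 0L))
    stop("every unit needs at least one trigger pattern")
  structure(lex, class = "content_lexicon")
}

#' Built-in Cookie Theft content-unit checklist
#'
#' A checklist of scorable content elements of the Cookie Theft scene
#' (people, objects, places and actions), shipped as package data so that
#' the unit inventory is configuration, not code. Replaceable via
#' \code{\link{read_content_lexicon}}.
#'
#' @return A \code{content_lexicon} with 23 units.
#' @export
default_content_lexicon <- function() {
  path <- system.file("extdata", "cookie_theft_units.yaml", package = "conlang")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "cookie_theft_units.yaml")
  read_content_lexicon(path)
}
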