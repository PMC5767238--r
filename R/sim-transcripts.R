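# Transcript generator with an exact oracle: a TranscriptPlan fixes the
# full composition of a sample (per-C-unit POS counts, maze schedule,
# relation counts, content units, unique-word target, duration), the
# generator realises a transcript with exactly that composition, and
# plan_features() evaluates every discourse measure from the plan in
# closed form. Feature extraction on the generated transcript must equal
# the plan oracle exactly.

CONTENT_POS <- c("noun", "verb", "pronoun", "adjective", "adverb",
                 "preposition", "conjunction", "determiner", "other")

#' Construct a transcript plan
#'
#' @param pos_counts Integer matrix (C-units x POS classes) of planned
#'   non-maze token counts; columns must be named from the content POS
#'   classes (noun, verb, pronoun, adjective, adverb, preposition,
#'   conjunction, determiner, other).
#' @param maze_counts Integer matrix (C-units x maze kinds) of planned
#'   maze events; columns named from filled_pause, unfilled_pause,
#'   repetition, revision, false_start. Defaults to none.
#' @param relation_counts Integer matrix (C-units x 2) with columns
#'   \code{embedding} and \code{total}; a C-unit with relations needs at
#'   least two planned tokens. Defaults to none.
#' @param content_units Character vector of lexicon unit ids the sample
#'   must mention (each realised as one noun token carrying the unit's
#'   first single-word trigger); the planned noun total must cover them.
#' @param unique_words Target number of distinct surfaces among content
#'   words; must lie between the number of mandatory fresh slots
#'   (content units + one per additional POS class used) and the total
#'   word count.
#' @param duration_s Planned sample duration in seconds.
#' @param seed Integer seed making generation reproducible.
#' @param participant_id,visit_id Identifiers for the generated sample.
#' @return A validated \code{transcript_plan} object.
#' @export
transcript_plan <- function(pos_counts, maze_counts = NULL,
                            relation_counts = NULL,
                            content_units = character(0),
                            unique_words, duration_s, seed = 1L,
                            participant_id = "SIM", visit_id = "V1") {
  pos_counts <- as.matrix(pos_counts)
  if (is.null(colnames(pos_counts)) ||
      !all(colnames(pos_counts) %in% CONTENT_POS))
    stop("pos_counts columns must be named from the content POS classes")
  full_pos <- matrix(0L, nrow(pos_counts), length(CONTENT_POS),
                     dimnames = list(NULL, CONTENT_POS))
  full_pos[, colnames(pos_counts)] <- as.integer(pos_counts)
  n_cu <- nrow(full_pos)
  if (n_cu < 1L) stop("plan needs at least one C-unit")
  if (any(full_pos < 0L)) stop("planned counts must be non-negative")

  full_maze <- matrix(0L, n_cu, length(MAZE_KINDS),
                      dimnames = list(NULL, MAZE_KINDS))
  if (!is.null(maze_counts)) {
    maze_counts <- as.matrix(maze_counts)
    if (is.null(colnames(maze_counts)) ||
        !all(colnames(maze_counts) %in% MAZE_KINDS))
      stop("maze_counts columns must be named from the maze kinds")
    if (nrow(maze_counts) != n_cu) stop("maze_counts row count mismatch")
    full_maze[, colnames(maze_counts)] <- as.integer(maze_counts)
    if (any(full_maze < 0L)) stop("planned maze counts must be non-negative")
  }

  full_rel <- matrix(0L, n_cu, 2L, dimnames = list(NULL, c("embedding", "total")))
  if (!is.null(relation_counts)) {
    relation_counts <- as.matrix(relation_counts)
    if (nrow(relation_counts) != n_cu) stop("relation_counts row count mismatch")
    full_rel[, colnames(relation_counts)] <- as.integer(relation_counts)
    if (any(full_rel < 0L)) stop("relation counts must be non-negative")
    if (any(full_rel[, "embedding"] > full_rel[, "total"]))
      stop("embedding relations cannot exceed total relations")
    need2 <- full_rel[, "total"] > 0L & rowSums(full_pos) < 2L
    if (any(need2))
      stop("C-unit(s) ", paste(which(need2), collapse = ", "),
           " plan relations but fewer than 2 tokens")
  }

  per_cu_tokens <- rowSums(full_pos)
  per_cu_events <- rowSums(full_maze)
  if (any(per_cu_tokens == 0L & per_cu_events == 0L))
    stop("every planned C-unit needs a content token or a maze event")

  total_words <- sum(full_pos)
  if (total_words < 1L) stop("plan has no content words")
  if (length(content_units) && anyDuplicated(content_units))
    stop("content_units must be distinct")
  if (length(content_units) > sum(full_pos[, "noun"]))
    stop("unsatisfiable plan: fewer planned nouns than content units")

  mandatory <- plan_mandatory_fresh(full_pos, length(content_units))
  if (unique_words > total_words)
    stop("unsatisfiable plan: unique_words > total_words")
  if (unique_words < mandatory)
    stop("unsatisfiable plan: unique_words below the ", mandatory,
         " mandatory distinct surfaces")
  if (duration_s <= 0) stop("duration_s must be positive")

  structure(list(pos_counts = full_pos, maze_counts = full_maze,
                 relation_counts = full_rel,
                 content_units = as.character(content_units),
                 unique_words = as.integer(unique_words),
                 duration_s = as.numeric(duration_s),
                 seed = as.integer(seed),
                 participant_id = participant_id, visit_id = visit_id),
            class = "transcript_plan")
}

# Minimum number of distinct surfaces a realisation must contain: one per
# content unit (triggers are distinct words) plus one for every non-empty
# POS class whose first slot cannot reuse an earlier same-class surface.
plan_mandatory_fresh <- function(pos_totals_matrix, n_units) {
  totals <- colSums(pos_totals_matrix)
  used <- names(totals)[totals > 0L]
  extra_noun <- if (n_units == 0L && "noun" %in% used) 1L else 0L
  n_units + length(setdiff(used, "noun")) + extra_noun
}

#' Closed-form feature oracle for a transcript plan
#'
#' Evaluates the count summary and the full feature vector analytically
#' from the plan, without generating a transcript. This is the exact
#' oracle the generated transcript must reproduce.
#'
#' @param p A \code{transcript_plan}.
#' @return List with elements \code{counts} (a \code{count_summary}) and
#'   \code{features} (a \code{feature_vector}).
#' @export
plan_features <- function(p) {
  stopifnot(inherits(p, "transcript_plan"))
  pos <- as.integer(colSums(p$pos_counts))
  names(pos) <- colnames(p$pos_counts)
  mz <- as.integer(colSums(p$maze_counts))
  names(mz) <- colnames(p$maze_counts)
  rel <- as.integer(colSums(p$relation_counts))
  names(rel) <- colnames(p$relation_counts)
  counts <- structure(list(
    total_words = sum(pos),
    unique_words = p$unique_words,
    n_utterances = nrow(p$pos_counts),
    nouns = pos[["noun"]], verbs = pos[["verb"]],
    pronouns = pos[["pronoun"]], adjectives = pos[["adjective"]],
    adverbs = pos[["adverb"]], prepositions = pos[["preposition"]],
    conjunctions = pos[["conjunction"]], determiners = pos[["determiner"]],
    filled_pauses = mz[["filled_pause"]],
    unfilled_pauses = mz[["unfilled_pause"]],
    repetitions = mz[["repetition"]], revisions = mz[["revision"]],
    false_starts = mz[["false_start"]],
    embedding_relations = rel[["embedding"]],
    total_relations = rel[["total"]],
    matched_content_units = length(p$content_units),
    duration_s = p$duration_s
  ), class = "count_summary")
  list(counts = counts, features = derive_features(counts))
}

#' Generate a transcript realising a plan exactly
#'
#' Builds a \code{\link{chat_transcript}} whose extracted counts equal
#' the plan, and returns it together with the plan's closed-form feature
#' vector. Content-unit triggers occupy the earliest noun slots; fresh
#' vocabulary is sampled without replacement until the unique-word target
#' is met, after which slots reuse an earlier same-class surface.
#' Generation is deterministic under \code{p$seed} (same seed,
#' byte-identical transcript) and leaves the caller's RNG state
#' untouched.
#'
#' @param p A \code{transcript_plan}.
#' @param lexicon Content-unit lexicon supplying trigger words; each
#'   planned unit needs a single-word trigger pattern.
#' @return List with elements \code{transcript} and \code{features}.
#' @export
generate_transcript <- function(p, lexicon = default_content_lexicon()) {
  stopifnot(inherits(p, "transcript_plan"))
  missing_u <- setdiff(p$content_units, names(lexicon))
  if (length(missing_u))
    stop("content units not in lexicon: ", paste(missing_u, collapse = ", "))
  triggers <- vapply(p$content_units, function(u) {
    single <- lexicon[[u]][!grepl(" ", lexicon[[u]], fixed = TRUE)]
    if (!length(single))
      stop("unit '", u, "' has no single-word trigger pattern")
    single[1]
  }, "")
  if (anyDuplicated(triggers))
    stop("unsatisfiable plan: duplicated trigger words across units")

  t_out <- run_seeded(p$seed, function() realise_plan(p, triggers))

  # guard the oracle: extraction must reproduce the plan exactly (this
  # also catches accidental extra content-unit matches)
  got <- tally_counts(t_out, lexicon)
  want <- plan_features(p)$counts
  if (!isTRUE(all.equal(unclass(got), unclass(want), tolerance = 0)))
    stop("unsatisfiable plan: realised transcript deviates from the plan oracle")
  list(transcript = t_out, features = plan_features(p)$features)
}

realise_plan <- function(p, triggers) {
  n_cu <- nrow(p$pos_counts)
  # global freshness schedule over content slots, in emission order
  slot_pos <- unlist(lapply(seq_len(n_cu), function(i) {
    rep(CONTENT_POS, times = p$pos_counts[i, ])
  }))
  n_slots <- length(slot_pos)
  is_trigger <- logical(n_slots)
  noun_idx <- which(slot_pos == "noun")
  if (length(triggers)) is_trigger[noun_idx[seq_along(triggers)]] <- TRUE

  fresh <- is_trigger
  # first slot of each class must be fresh
  for (cl in unique(slot_pos)) {
    first <- which(slot_pos == cl)[1]
    if (!is_trigger[first]) fresh[first] <- TRUE
  }
  budget <- p$unique_words - sum(fresh)
  if (budget < 0L) stop("unsatisfiable plan: mandatory fresh slots exceed unique_words")
  for (k in seq_len(n_slots)) {
    if (budget == 0L) break
    if (!fresh[k]) { fresh[k] <- TRUE; budget <- budget - 1L }
  }

  vocab_counter <- new.env(parent = emptyenv())
  used <- lapply(setNames(vector("list", length(CONTENT_POS)), CONTENT_POS),
                 function(x) character(0))
  surfaces <- character(n_slots)
  trig_i <- 0L
  for (k in seq_len(n_slots)) {
    cl <- slot_pos[k]
    if (is_trigger[k]) {
      trig_i <- trig_i + 1L
      w <- triggers[[trig_i]]
    } else if (fresh[k]) {
      i <- (get0(cl, envir = vocab_counter, ifnotfound = 0L)) + 1L
      assign(cl, i, envir = vocab_counter)
      w <- sprintf("%s%04d", substr(cl, 1, 4), i)
    } else {
      pool <- used[[cl]]
      w <- pool[if (length(pool) == 1L) 1L else sample.int(length(pool), 1L)]
    }
    surfaces[k] <- w
    if (!(w %in% used[[cl]])) used[[cl]] <- c(used[[cl]], w)
  }

  cunits <- vector("list", n_cu)
  slot_at <- 0L
  alt_i <- 0L; start_i <- 0L
  for (i in seq_len(n_cu)) {
    n_tok <- sum(p$pos_counts[i, ])
    cu_pos <- rep(CONTENT_POS, times = p$pos_counts[i, ])
    cu_surf <- surfaces[slot_at + seq_len(n_tok)]
    slot_at <- slot_at + n_tok

    tokens <- list(); events <- list()
    mk <- p$maze_counts[i, ]
    for (r in seq_len(mk[["false_start"]])) {
      start_i <- start_i + 1L
      tokens[[length(tokens) + 1L]] <-
        chat_token(sprintf("fstart%03d", start_i), pos = "other", in_maze = TRUE)
      events[[length(events) + 1L]] <-
        maze_event("false_start", token_span = length(tokens))
    }
    for (r in seq_len(mk[["repetition"]])) {
      w <- if (n_tok > 0L) cu_surf[1] else "uh"
      tokens[[length(tokens) + 1L]] <-
        chat_token(w, pos = "other", in_maze = TRUE)
      events[[length(events) + 1L]] <-
        maze_event("repetition", token_span = length(tokens))
    }
    for (r in seq_len(mk[["revision"]])) {
      alt_i <- alt_i + 1L
      tokens[[length(tokens) + 1L]] <-
        chat_token(sprintf("revis%03d", alt_i), pos = "other", in_maze = TRUE)
      events[[length(events) + 1L]] <-
        maze_event("revision", token_span = length(tokens))
    }
    for (r in seq_len(mk[["filled_pause"]])) {
      tokens[[length(tokens) + 1L]] <-
        chat_token("um", pos = "nonword", is_filled_pause = TRUE)
      events[[length(events) + 1L]] <-
        maze_event("filled_pause", token_span = length(tokens))
    }
    for (r in seq_len(mk[["unfilled_pause"]])) {
      events[[length(events) + 1L]] <-
        maze_event("unfilled_pause", after_token = length(tokens))
    }
    for (k in seq_len(n_tok)) {
      tokens[[length(tokens) + 1L]] <-
        chat_token(cu_surf[k], pos = cu_pos[k])
    }

    rels <- list()
    n_rel <- p$relation_counts[i, "total"]
    n_emb <- p$relation_counts[i, "embedding"]
    if (n_rel > 0L) {
      for (r in seq_len(n_rel)) {
        dep <- 1L + (r - 1L) %% (n_tok - 1L)
        rels[[r]] <- gram_relation(if (r <= n_emb) "COMP" else "SUBJ",
                                   head_index = dep + 1L,
                                   dependent_index = dep)
      }
    }
    cunits[[i]] <- cunit(tokens, rels, events, terminator = ".")
  }
  chat_transcript(p$participant_id, p$visit_id, p$duration_s, cunits)
}

# run fn() under set.seed(seed), restoring the caller's RNG state
run_seeded <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Draw a random, always-satisfiable transcript plan
#'
#' Samples a plan with 3-8 C-units, realistic POS mixes, a random maze
#' schedule, relation counts, 3-8 content units (from the lexicon's
#' single-word-trigger units) and a feasible unique-word target.
#' Deterministic under \code{seed}; leaves the caller's RNG state
#' untouched.
#'
#' @param seed Integer seed.
#' @param lexicon Content-unit lexicon to draw unit ids from.
#' @return A \code{transcript_plan}.
#' @export
random_transcript_plan <- function(seed, lexicon = default_content_lexicon()) {
  run_seeded(seed, function() {
    n_cu <- sample(3:8, 1)
    pos <- cbind(noun = sample(1:4, n_cu, TRUE),
                 verb = sample(0:3, n_cu, TRUE),
                 pronoun = sample(0:2, n_cu, TRUE),
                 adjective = sample(0:2, n_cu, TRUE),
                 adverb = sample(0:2, n_cu, TRUE),
                 preposition = sample(0:2, n_cu, TRUE),
                 conjunction = sample(0:1, n_cu, TRUE),
                 determiner = sample(0:2, n_cu, TRUE))
    maze <- cbind(filled_pause = rbinom(n_cu, 2, 0.3),
                  unfilled_pause = rbinom(n_cu, 2, 0.2),
                  repetition = rbinom(n_cu, 1, 0.25),
                  revision = rbinom(n_cu, 1, 0.25),
                  false_start = rbinom(n_cu, 1, 0.15))
    n_tok <- rowSums(pos)
    tot_rel <- vapply(n_tok, function(n)
      if (n >= 2L) sample(0:(n - 1L), 1) else 0L, integer(1))
    emb <- vapply(tot_rel, function(n)
      if (n >= 1L) sample(0:n, 1) else 0L, integer(1))
    rel <- cbind(embedding = emb, total = tot_rel)

    singles <- names(lexicon)[vapply(lexicon, function(p)
      any(!grepl(" ", p, fixed = TRUE)), logical(1))]
    trig_words <- vapply(singles, function(u)
      lexicon[[u]][!grepl(" ", lexicon[[u]], fixed = TRUE)][1], "")
    singles <- singles[!duplicated(trig_words)]
    n_units <- min(sample(3:8, 1), sum(pos[, "noun"]), length(singles))
    units <- sample(singles, n_units)

    mandatory <- plan_mandatory_fresh(pos, n_units)
    uw <- sample(seq.int(mandatory, sum(pos)), 1)
    transcript_plan(pos, maze, rel, content_units = units,
                    unique_words = uw,
                    duration_s = round(runif(1, 30, 90), 1),
                    seed = seed,
                    participant_id = sprintf("SIM%05d", seed))
  })
}
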