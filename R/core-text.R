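# Core text handling: tokenization, surface counts, syllables, n-grams.
# All downstream feature families and scorers share these primitives.

#' Default filler-word inventory
#'
#' Hesitation markers counted by [tokenize_and_count()]. Matching is
#' case-insensitive against lowercased tokens.
#'
#' @return Character vector of filler words.
#' @export
default_fillers <- function() c("uh", "um", "er", "ah", "hm", "mhm")

#' Tokenize text
#'
#' Deterministic transcript-style tokenization: lowercase, split on
#' whitespace, strip leading/trailing punctuation, keep word-internal
#' apostrophes and hyphens. Empty fragments are dropped.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- strsplit(tolower(text), "\\s+")[[1]]
  toks <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", raw)
  toks[nzchar(toks)]
}

#' Split typed text into sentences
#'
#' Sentences end at `.`, `!` or `?` followed by whitespace or end of input.
#' For spoken transcripts each utterance is treated as one sentence instead
#' (see [as_transcript()]).
#'
#' @param text Character scalar.
#' @return Character vector of sentence strings.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(gsub("[^[:alnum:]]", "", parts))]
}

#' Build a transcript object
#'
#' A transcript is an ordered list of utterances (each a character vector of
#' tokens) carrying subject/session/task/stimulus identity.
#'
#' @param utterances List of non-empty character token vectors.
#' @param subject_id,session_id,task,stimulus_id Identifiers (non-empty).
#' @return An object of class `transcript`.
#' @export
as_transcript <- function(utterances, subject_id = "s1", session_id = "1",
                          task = "unknown", stimulus_id = "stim1") {
  stopifnot(is.list(utterances), length(utterances) >= 1L)
  if (any(!vapply(utterances, function(u) is.character(u) && length(u) >= 1L, TRUE)))
    stop("every utterance must be a nonempty character token vector")
  ids <- c(subject_id, session_id, task, stimulus_id)
  if (any(!nzchar(ids))) stop("identifiers must be nonempty")
  structure(
    list(utterances = utterances, subject_id = subject_id,
         session_id = session_id, task = task, stimulus_id = stimulus_id),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> subject=%s session=%s task=%s stimulus=%s: %d utterance(s), %d tokens\n",
              x$subject_id, x$session_id, x$task, x$stimulus_id,
              length(x$utterances), length(unlist(x$utterances))))
  invisible(x)
}

#' Tokenize a sample and compute its surface counts
#'
#' Produces the token/type/hapax/sentence/syllable/filler counts that feed
#' the vocabulary-richness and readability features.
#'
#' @param x UTF-8 text (character scalar) or a `transcript`. For text,
#'   sentences are split on terminal punctuation; for a transcript each
#'   utterance counts as one sentence.
#' @param fillers Lowercase filler inventory; defaults to
#'   [default_fillers()].
#' @return A list with elements `counts` (named numeric: `n_tokens`,
#'   `n_types`, `n_hapax`, `n_sentences`, `n_syllables`, `n_fillers`,
#'   `mean_word_chars`, `mean_word_syllables`) and `transcript`.
#'   Empty/whitespace-only input signals a classed
#'   `langscore_empty_sample` error rather than returning degenerate zeros.
#' @export
tokenize_and_count <- function(x, fillers = default_fillers()) {
  stopifnot(is.character(fillers))
  fillers <- tolower(fillers)
  if (inherits(x, "transcript")) {
    tr <- x
    utts <- lapply(tr$utterances, function(u) tolower(u))
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    if (!nzchar(trimws(x))) stop(empty_sample_error())
    sents <- split_sentences(x)
    utts <- lapply(sents, tokenize)
    utts <- utts[vapply(utts, length, 1L) > 0L]
    if (length(utts) == 0L) stop(empty_sample_error())
    tr <- as_transcript(utts)
  }
  toks <- unlist(utts)
  if (length(toks) == 0L) stop(empty_sample_error())
  tab <- table(toks)
  word_toks <- toks[grepl("[a-z]", toks)]
  syl <- if (length(word_toks)) {
    vapply(word_toks, function(w) count_syllables(gsub("[^a-z]", "", w)), 1L)
  } else integer(0)
  counts <- c(
    n_tokens = length(toks),
    n_types = length(tab),
    n_hapax = sum(tab == 1L),
    n_sentences = length(utts),
    n_syllables = sum(syl),
    n_fillers = sum(toks %in% fillers),
    mean_word_chars = mean(nchar(toks)),
    mean_word_syllables = if (length(syl)) mean(syl) else NA_real_
  )
  list(counts = counts, transcript = tr)
}

#' Count syllables in a word
#'
#' Heuristic syllabification used by the Flesch-family readability scores:
#' the number of maximal vowel-letter groups (a, e, i, o, u, y), minus one
#' for a trailing silent "e" (unless the word ends in "le"), with a floor of
#' one syllable.
#'
#' @param word Non-empty alphabetic character scalar.
#' @return Integer syllable count (>= 1).
#' @export
count_syllables <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  w <- tolower(word)
  if (!nzchar(w) || grepl("[^a-z]", w)) stop("count_syllables expects a nonempty alphabetic word")
  groups <- gregexpr("[aeiouy]+", w)[[1]]
  n <- if (groups[1] == -1L) 0L else length(groups)
  if (n > 1L && grepl("e$", w) && !grepl("le$", w)) n <- n - 1L
  max(n, 1L)
}

#' Extract contiguous n-grams
#'
#' N-grams never cross utterance boundaries: pass a list of token vectors to
#' respect them, or a single token vector for one segment. Multiplicities
#' are preserved.
#'
#' @param tokens Character vector, or list of character vectors (utterances).
#' @param n N-gram order (>= 1).
#' @return Character vector of space-joined n-grams (a multiset; possibly
#'   empty when segments are shorter than `n`).
#' @export
extract_ngrams <- function(tokens, n) {
  stopifnot(length(n) == 1L, is.numeric(n))
  if (n < 1) stop("n-gram order must be >= 1")
  n <- as.integer(n)
  segs <- if (is.list(tokens)) tokens else list(tokens)
  out <- lapply(segs, function(tk) {
    L <- length(tk)
    if (L < n) return(character(0))
    vapply(seq_len(L - n + 1L),
           function(i) paste(tk[i:(i + n - 1L)], collapse = " "), "")
  })
  unlist(out, use.names = FALSE)
}
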