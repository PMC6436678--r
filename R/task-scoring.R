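# The six task scorers: image naming (Wu-Palmer vs. image annotations),
# picture description (information-content-unit detection), verbal fluency
# (in/out-of-category counts), story recall (ROUGE-n), vocabulary (BLEU),
# and the binary choice tasks (pronoun-resolution schemas, yes/no
# depression-screen items, mood rating).

#' Score an image-naming response
#'
#' The typed response and each image annotation are mapped to their
#' most-frequent taxonomy sense and compared with Wu-Palmer similarity;
#' the score is the maximum over annotations, in \[0, 1\]. An
#' out-of-vocabulary or empty response scores 0. Session-level scores are
#' means over stimuli (see [score_sessions()]).
#'
#' @param response Single response word (tokenized internally; first token
#'   used).
#' @param annotations Nonempty character vector of annotation words.
#' @param tax A [taxonomy()].
#' @return Numeric score in \[0, 1\].
#' @export
score_image_naming <- function(response, annotations, tax) {
  stopifnot(length(annotations) >= 1L, inherits(tax, "taxonomy"))
  toks <- tokenize(response %||% "")
  if (!length(toks)) {
    warning("empty image-naming response scored 0")
    return(0)
  }
  rs <- word_senses(tax, toks[1], "most_frequent")
  if (!length(rs)) return(0)
  best <- 0
  for (a in annotations) {
    as_ <- word_senses(tax, a, "most_frequent")
    if (!length(as_)) next
    v <- pairwise_similarity(tax, rs, as_, "wup")$value
    if (v > best) best <- v
  }
  best
}

#' Information-content-unit specification
#'
#' @param icus Character vector of ICU phrases (each 1..m space-separated
#'   words).
#' @param manual_synonyms Named list: ICU phrase -> character vector of
#'   manually-added synonym words (accepted verbatim).
#' @param threshold Similarity acceptance threshold in (0, 1\]; the
#'   comparison is strict (`> threshold`). Default 0.75.
#' @return Object of class `icu_spec`.
#' @export
icu_spec <- function(icus, manual_synonyms = list(), threshold = 0.75) {
  stopifnot(is.character(icus), length(icus) >= 1L, all(nzchar(icus)),
            threshold > 0, threshold <= 1)
  structure(list(icus = icus, manual_synonyms = manual_synonyms,
                 threshold = threshold), class = "icu_spec")
}

#' Detect information content units in a transcript
#'
#' A single-word ICU is detected when some transcript word matches it
#' verbatim, is a listed manual synonym, or has taxonomy similarity
#' strictly above the threshold under the Lin measure, maximized over all
#' sense pairs. A multi-word ICU of `m` words is compared against every
#' contiguous transcript window of `n <= m` words by solving a
#' maximum-weight bipartite assignment on the pairwise word similarities;
#' it is detected when every matched pair exceeds the threshold (greedy
#' pairing can miss detections the optimal pairing finds). Each ICU counts
#' at most once; the detected count is the picture-description information
#' score.
#'
#' @param x A `transcript`, or a character vector of tokens.
#' @param spec An [icu_spec()].
#' @param tax A [taxonomy()].
#' @param measure Similarity measure for word pairs (default `"lin"`).
#' @return List with `detected` (character vector of detected ICU phrases)
#'   and `count`.
#' @export
detect_icus <- function(x, spec, tax, measure = "lin") {
  stopifnot(inherits(spec, "icu_spec"), inherits(tax, "taxonomy"))
  toks <- if (inherits(x, "transcript")) unlist(x$utterances) else x
  toks <- tolower(toks)
  thr <- spec$threshold
  sim1 <- function(icu_word, word) {
    if (word == icu_word) return(1)
    s <- word_similarity(tax, icu_word, word, measure = measure, senses = "all")
    if (is.na(s)) 0 else s
  }
  detected <- character(0)
  for (phrase in spec$icus) {
    icu_words <- tolower(strsplit(phrase, "\\s+")[[1]])
    m <- length(icu_words)
    syns <- tolower(spec$manual_synonyms[[phrase]] %||% character(0))
    hit <- FALSE
    if (m == 1L) {
      for (wd in unique(toks)) {
        if (wd %in% syns || sim1(icu_words, wd) > thr) { hit <- TRUE; break }
      }
    } else {
      if (length(syns) && any(toks %in% syns)) hit <- TRUE
      nt <- length(toks)
      for (n in seq_len(m)) {
        if (hit || nt < n) break
        for (start in seq_len(nt - n + 1L)) {
          window <- toks[start:(start + n - 1L)]
          w <- matrix(0, m, n)
          for (i in seq_len(m)) for (j in seq_len(n))
            w[i, j] <- sim1(icu_words[i], window[j])
          sol <- max_weight_assignment(w)
          pairw <- w[cbind(sol$pairs, seq_len(n))]
          if (all(pairw > thr)) { hit <- TRUE; break }
        }
      }
    }
    if (hit) detected <- c(detected, phrase)
  }
  list(detected = detected, count = length(detected))
}

#' Score a verbal-fluency response list
#'
#' Responses are deduplicated case-insensitively. Semantic mode: a word is
#' in-category when it appears in the stimulus dictionary, or failing
#' that, when the category concept is an ancestor (hypernym) of any of its
#' taxonomy senses; every other unique word counts as out-of-category.
#' Letter mode: a word is valid only if it exists in the validity lexicon
#' (nonwords are discarded); valid words are in-category when they start
#' with the letter, out-of-category otherwise.
#'
#' @param responses Character vector of response words.
#' @param category Category concept identifier (semantic mode) or a single
#'   letter (letter mode).
#' @param mode `"semantic"` or `"letter"`.
#' @param dictionary Character vector of known in-category words (semantic
#'   mode).
#' @param tax A [taxonomy()] (semantic hypernym check).
#' @param lexicon Character vector of valid words (letter mode); defaults
#'   to the taxonomy's sense-map vocabulary.
#' @return Named integer vector `c(in_category, out_of_category)`.
#' @export
score_fluency <- function(responses, category, mode = c("semantic", "letter"),
                          dictionary = character(0), tax = NULL, lexicon = NULL) {
  mode <- match.arg(mode)
  words <- unique(tolower(responses[nzchar(trimws(responses))]))
  if (!length(words)) return(c(in_category = 0L, out_of_category = 0L))
  if (mode == "semantic") {
    stopifnot(inherits(tax, "taxonomy"))
    in_cat <- vapply(words, function(wd) {
      if (wd %in% tolower(dictionary)) return(TRUE)
      any(vapply(word_senses(tax, wd, "all"),
                 function(s) category %in% tax_ancestors(tax, s), TRUE))
    }, TRUE)
    c(in_category = sum(in_cat), out_of_category = sum(!in_cat))
  } else {
    if (is.null(lexicon)) {
      stopifnot(inherits(tax, "taxonomy"))
      lexicon <- names(tax$senses)
    }
    valid <- words[words %in% tolower(lexicon)]
    in_cat <- startsWith(valid, tolower(category))
    c(in_category = sum(in_cat), out_of_category = sum(!in_cat))
  }
}

#' ROUGE-n recall score for story retelling
#'
#' Clipped matched n-gram count divided by the reference n-gram count:
#' each reference n-gram can be credited at most as often as it occurs in
#' the candidate.
#'
#' @param candidate,reference Character token vectors (reference
#'   nonempty).
#' @param n N-gram order, 1 or 2.
#' @return Numeric recall in \[0, 1\]; NA when the reference is shorter
#'   than `n`.
#' @export
rouge_score <- function(candidate, reference, n = 1L) {
  stopifnot(length(reference) >= 1L, n %in% c(1L, 2L))
  ref_ng <- extract_ngrams(reference, n)
  if (!length(ref_ng)) return(NA_real_)
  cand_ng <- extract_ngrams(candidate, n)
  ref_tab <- table(ref_ng)
  cand_tab <- table(cand_ng)
  common <- intersect(names(ref_tab), names(cand_tab))
  matched <- sum(pmin(ref_tab[common], cand_tab[common]))
  as.numeric(matched / length(ref_ng))
}

#' BLEU precision score for typed definitions
#'
#' Brevity penalty `BP = 1` if `r < c`, else `exp(1 - r/c)`, where `c` is
#' the candidate length and `r` the reference length nearest to `c` (ties
#' broken toward the shorter reference, the harsher penalty). Per-order
#' precision `p_n = C_n / N` with `C_n` the clipped count of candidate
#' n-grams found in at least one reference. The denominator `N` defaults
#' to the candidate word count at every order
#' (`denominator = "words"`); `"ngrams"` selects the conventional
#' denominator (the candidate's n-gram count at order n). The score is
#' `BP * (p_1 ... p_max_n)^(1/max_n)`, 0 when any `p_n` is 0.
#'
#' @param candidate Character token vector; empty scores 0.
#' @param references List of character token vectors (at least one).
#' @param max_n Maximum n-gram order (>= 1).
#' @param denominator `"words"` or `"ngrams"` (see above).
#' @return List with `score` and `computation` (c, r, brevity penalty,
#'   per-order precisions and matched counts).
#' @export
bleu_score <- function(candidate, references, max_n = 2L,
                       denominator = c("words", "ngrams")) {
  denominator <- match.arg(denominator)
  stopifnot(is.list(references), length(references) >= 1L, max_n >= 1L)
  cc <- length(candidate)
  comp <- list(c = cc, r = NA_integer_, bp = NA_real_,
               p_n = rep(NA_real_, max_n), matched = rep(NA_real_, max_n))
  if (cc == 0L) return(list(score = 0, computation = comp))
  ref_lens <- vapply(references, length, 1L)
  ord <- order(abs(ref_lens - cc), ref_lens)
  r <- ref_lens[ord[1]]
  bp <- if (r < cc) 1 else exp(1 - r / cc)
  p <- numeric(max_n); matched <- numeric(max_n)
  for (n in seq_len(max_n)) {
    cand_ng <- extract_ngrams(candidate, n)
    if (!length(cand_ng)) { p[n] <- 0; matched[n] <- 0; next }
    cand_tab <- table(cand_ng)
    # clip against the maximum count of the n-gram in any single reference
    ref_max <- sapply(names(cand_tab), function(g) {
      max(vapply(references, function(rf) sum(extract_ngrams(rf, n) == g), 1.0))
    })
    Cn <- sum(pmin(as.numeric(cand_tab), ref_max))
    N <- if (denominator == "words") cc else length(cand_ng)
    matched[n] <- Cn
    p[n] <- Cn / N
  }
  score <- if (any(p == 0)) 0 else bp * prod(p)^(1 / max_n)
  comp <- list(c = cc, r = r, bp = bp, p_n = p, matched = matched)
  list(score = score, computation = comp)
}

#' Score binary-choice and self-report tasks
#'
#' Pronoun-resolution (Winograd-style) items score 1 for the keyed answer
#' and 0 otherwise. Depression-screen yes/no items map to 0/1 using the
#' per-item polarity in the key (`"yes"` scoring 1 when
#' `polarity = "yes"`, and symmetrically). Mood ratings on \[1, 10\] pass
#' through unchanged.
#'
#' @param responses Data frame with columns `stimulus_id`, `response`.
#' @param answer_key Data frame with columns `stimulus_id`, `type`
#'   (`"choice"`, `"yesno"`, `"mood"`), and `answer` (correct choice, or
#'   the polarity `"yes"`/`"no"` for yes/no items; ignored for mood).
#' @return Data frame `stimulus_id`, `value`.
#' @export
score_choice_tasks <- function(responses, answer_key) {
  stopifnot(all(c("stimulus_id", "response") %in% names(responses)),
            all(c("stimulus_id", "type", "answer") %in% names(answer_key)))
  unknown <- setdiff(responses$stimulus_id, answer_key$stimulus_id)
  if (length(unknown))
    stop("responses to unknown stimuli: ", paste(unknown, collapse = ", "))
  key <- answer_key[match(responses$stimulus_id, answer_key$stimulus_id), ]
  value <- numeric(nrow(responses))
  for (i in seq_len(nrow(responses))) {
    resp <- tolower(trimws(as.character(responses$response[i])))
    value[i] <- switch(key$type[i],
      choice = as.numeric(resp == tolower(key$answer[i])),
      yesno = {
        yes <- as.numeric(resp %in% c("yes", "y", "1", "true"))
        if (tolower(key$answer[i]) == "yes") yes else 1 - yes
      },
      mood = {
        v <- suppressWarnings(as.numeric(resp))
        if (is.na(v) || v < 1 || v > 10) stop("mood rating must be on [1, 10]")
        v
      },
      stop("unknown item type: ", key$type[i])
    )
  }
  data.frame(stimulus_id = responses$stimulus_id, value = value,
             stringsAsFactors = FALSE)
}
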