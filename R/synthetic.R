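# Seeded synthetic-fixture generators: every input the pipeline consumes
# (taxonomies, norm/polarity lexicons, transcripts with alignments and tags,
# score cohorts) can be generated offline with known ground truth. One
# master seed fans out to independent per-generator streams via
# derive_seed(), so generators are bit-reproducible and order-independent.

#' Generate a random rooted is-a taxonomy
#'
#' Random tree rooted at `"root"` with Zipf-distributed concept counts and
#' a word-to-sense map with controlled polysemy; every non-root concept
#' receives at least one word when `vocabulary_size >= n_concepts - 1`.
#' `mode = "chain"` instead yields the degenerate chain
#' root -> a -> b -> ... used for hand-checked depth/similarity examples.
#'
#' @param n_concepts Number of concepts (>= 2), root included.
#' @param branching Maximum children per concept (>= 1).
#' @param vocabulary_size Number of words in the sense map.
#' @param seed Integer seed.
#' @param mode `"random"` or `"chain"`.
#' @param polysemy_prob Probability that a word carries extra senses.
#' @return A [taxonomy()].
#' @export
gen_taxonomy <- function(n_concepts, branching = 3L, vocabulary_size = 2L * n_concepts,
                         seed = 0L, mode = c("random", "chain"),
                         polysemy_prob = 0.3) {
  mode <- match.arg(mode)
  stopifnot(n_concepts >= 2L)
  if (branching < 1L) stop("branching must be >= 1")
  with_seed(derive_seed(seed, "taxonomy"), {
    concepts <- c("root", sprintf("c%03d", seq_len(n_concepts - 1L)))
    if (mode == "chain") {
      edges <- data.frame(child = concepts[-1], parent = concepts[-n_concepts])
    } else {
      parent <- character(n_concepts - 1L)
      n_kids <- stats::setNames(integer(n_concepts), concepts)
      for (i in seq_len(n_concepts - 1L)) {
        open <- concepts[seq_len(i)][n_kids[seq_len(i)] < branching]
        p <- if (length(open) == 1L) open else sample(open, 1L)
        parent[i] <- p
        n_kids[p] <- n_kids[p] + 1L
      }
      edges <- data.frame(child = concepts[-1], parent = parent)
    }
    rank <- sample(n_concepts)
    counts <- stats::setNames(round(1000 / rank), concepts)
    nonroot <- concepts[-1]
    senses <- list()
    if (vocabulary_size > 0L) {
      primary <- nonroot[(seq_len(vocabulary_size) - 1L) %% length(nonroot) + 1L]
      for (i in seq_len(vocabulary_size)) {
        s <- primary[i]
        if (stats::runif(1) < polysemy_prob && length(nonroot) > 1L)
          s <- c(s, sample(setdiff(nonroot, s), sample(1:2, 1L)))
        senses[[sprintf("w%03d", i)]] <- s
      }
    }
    taxonomy(edges, counts, senses)
  })
}

#' Generate synthetic norm and polarity lexicons
#'
#' Seven norm dimensions with values in realistic ranges (frequency
#' 0.1-7 log-units, age-of-acquisition 2-17 years, imageability and
#' familiarity 1-7, arousal/dominance/valence 1-9) and a four-category
#' polarity lexicon. `coverage` controls the fraction of the vocabulary
#' present in each lexicon; `constant` makes every value the dimension's
#' midpoint (useful for zero-variance checks).
#'
#' @param vocabulary Character vector of words.
#' @param seed Integer seed.
#' @param coverage Per-lexicon inclusion probability in (0, 1\].
#' @param constant Use constant values instead of random ones.
#' @return List with `norms` (list of [norm_lexicon()]) and `polarity`
#'   (a [polarity_lexicon()]).
#' @export
gen_lexicons <- function(vocabulary, seed = 0L, coverage = 1, constant = FALSE) {
  stopifnot(length(vocabulary) >= 1L, coverage > 0, coverage <= 1)
  ranges <- list(frequency = c(0.1, 7), aoa = c(2, 17), imageability = c(1, 7),
                 familiarity = c(1, 7), arousal = c(1, 9), dominance = c(1, 9),
                 valence = c(1, 9))
  with_seed(derive_seed(seed, "lexicons"), {
    norms <- lapply(names(ranges), function(d) {
      r <- ranges[[d]]
      keep <- vocabulary[stats::runif(length(vocabulary)) <= coverage]
      if (!length(keep)) keep <- vocabulary[1]
      vals <- if (constant) rep(mean(r), length(keep)) else stats::runif(length(keep), r[1], r[2])
      norm_lexicon(d, stats::setNames(vals, keep))
    })
    names(norms) <- names(ranges)
    cats <- c("strong negative", "weak negative", "weak positive", "strong positive")
    keep <- vocabulary[stats::runif(length(vocabulary)) <= coverage]
    if (!length(keep)) keep <- vocabulary[1]
    pol <- polarity_lexicon(stats::setNames(sample(cats, length(keep), replace = TRUE), keep))
    list(norms = norms, polarity = pol)
  })
}

#' Generate a synthetic task response with known ground truth
#'
#' Produces a transcript (plus word alignment with planted pauses and a
#' pre-tagged rendering) whose measurable properties are monotone in
#' `quality` on \[0, 1\]:
#' \describe{
#'   \item{picture_description}{mentions `round(quality * n_icus)` of the
#'     stimulus ICUs (verbatim), interleaved with out-of-taxonomy
#'     distractor words.}
#'   \item{recall}{retells the first `ceiling(quality * length)` tokens of
#'     the source story verbatim (quality 1 = full retelling).}
#'   \item{fluency}{lists `round(quality * n)` in-category dictionary
#'     words and a few distractors.}
#'   \item{vocabulary}{types the first `ceiling(quality * length)` tokens
#'     of the reference definition.}
#' }
#'
#' @param task One of `"picture_description"`, `"recall"`, `"fluency"`,
#'   `"vocabulary"`.
#' @param resources Task resources: `icus` (character vector),
#'   `story`/`definition` (token vector), `dictionary` (character
#'   vector), as the task requires.
#' @param quality Real in \[0, 1\].
#' @param seed Integer seed.
#' @param gaps Inter-word silence gaps (seconds) cycled through when
#'   planting the alignment; defaults to `c(0.05, 0.2, 0.5)`.
#' @param word_dur Per-word duration in seconds.
#' @return List: `transcript`, `alignment` (data frame), `tagged`
#'   (token/TAG string), `ground_truth` (task-specific).
#' @export
gen_transcript <- function(task, resources, quality = 1, seed = 0L,
                           gaps = c(0.05, 0.2, 0.5), word_dur = 0.3) {
  stopifnot(quality >= 0, quality <= 1)
  task <- match.arg(task, c("picture_description", "recall", "fluency", "vocabulary"))
  with_seed(derive_seed(seed, paste0("transcript_", task)), {
    distractor <- function(k) if (k > 0) sprintf("xq%02dz", sample(99, k, replace = TRUE)) else character(0)
    gt <- list(quality = quality)
    toks <- switch(task,
      picture_description = {
        icus <- resources$icus
        n_icu <- round(quality * length(icus))
        mention <- if (n_icu > 0) icus[seq_len(n_icu)] else character(0)
        gt$icus_mentioned <- mention
        out <- unlist(lapply(mention, function(p) strsplit(p, "\\s+")[[1]]))
        c(out, distractor(3L))  # ICU phrases stay contiguous; distractors trail
      },
      recall = {
        story <- resources$story
        keep <- ceiling(quality * length(story))
        gt$fraction_retold <- keep / length(story)
        if (keep > 0) story[seq_len(keep)] else distractor(3L)
      },
      fluency = {
        dict <- resources$dictionary
        n_in <- round(quality * length(dict))
        gt$n_in_category <- n_in
        out <- distractor(2L)
        gt$n_out_category <- length(out)
        c(if (n_in > 0) dict[seq_len(n_in)] else character(0), out)
      },
      vocabulary = {
        def <- resources$definition
        keep <- ceiling(quality * length(def))
        if (keep > 0) def[seq_len(keep)] else distractor(3L)
      }
    )
    if (!length(toks)) toks <- distractor(3L)
    toks <- tolower(toks)
    # utterances of ~5 tokens each
    split_idx <- ceiling(seq_along(toks) / 5)
    utts <- unname(split(toks, split_idx))
    tr <- as_transcript(utts, task = task)
    g <- rep_len(gaps, max(length(toks) - 1L, 0L))
    onset <- cumsum(c(0, rep(word_dur, length(toks) - 1L) + g))
    alignment <- data.frame(word = toks, onset_s = onset,
                            offset_s = onset + word_dur)
    tags <- ifelse(grepl("^xq", toks), "NN",
                   sample(c("NN", "VB", "JJ", "DT", "IN"), length(toks),
                          replace = TRUE, prob = c(0.4, 0.25, 0.15, 0.1, 0.1)))
    tagged <- paste(paste0(toks, "/", tags), collapse = " ")
    list(transcript = tr, alignment = alignment, tagged = tagged,
         ground_truth = gt)
  })
}

#' Specify a synthetic score cohort
#'
#' Scores follow a subject-ability x stimulus-difficulty model:
#' `score(i, task, s) = loading_task * ability_i + difficulty_s + noise`,
#' with `ability ~ N(0, sigma_ability)`, per-(task, stimulus)
#' `difficulty ~ N(0, sigma_difficulty)` and
#' `noise ~ N(0, sigma_noise)`. Binary tasks push the linear predictor
#' through a logistic link and draw Bernoulli outcomes.
#'
#' @param n_subjects,n_sessions,n_stimuli Cohort dimensions.
#' @param task_loadings Named numeric vector: task -> loading on the
#'   shared ability.
#' @param sigma_ability,sigma_difficulty,sigma_noise Positive standard
#'   deviations.
#' @param binary_tasks Subset of task names scored 0/1 via the logistic
#'   link.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100L, n_sessions = 1L, n_stimuli = 10L,
                        task_loadings = c(picture_description = 1, recall = 0.8),
                        sigma_ability = 1, sigma_difficulty = 1, sigma_noise = 0.5,
                        binary_tasks = character(0), seed = 0L) {
  stopifnot(sigma_ability > 0, sigma_difficulty >= 0, sigma_noise > 0,
            !is.null(names(task_loadings)))
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 n_stimuli = n_stimuli, task_loadings = task_loadings,
                 sigma_ability = sigma_ability, sigma_difficulty = sigma_difficulty,
                 sigma_noise = sigma_noise, binary_tasks = binary_tasks,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic score cohort with known latent structure
#'
#' @param spec A [cohort_spec()].
#' @return List: `scores` (data frame `subject_id`, `session_id`, `task`,
#'   `stimulus_id`, `metric`, `value`), `ability` (named vector of true
#'   subject abilities), `difficulty` (named vector of true per-stimulus
#'   difficulties).
#' @export
gen_score_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$seed, "cohort"), {
    subj <- sprintf("s%04d", seq_len(spec$n_subjects))
    ability <- stats::setNames(stats::rnorm(spec$n_subjects, 0, spec$sigma_ability), subj)
    rows <- list()
    difficulty <- numeric(0)
    for (task in names(spec$task_loadings)) {
      stims <- sprintf("%s_stim%02d", task, seq_len(spec$n_stimuli))
      diff_s <- stats::setNames(stats::rnorm(spec$n_stimuli, 0, spec$sigma_difficulty), stims)
      difficulty <- c(difficulty, diff_s)
      lt <- spec$task_loadings[[task]]
      for (sess in seq_len(spec$n_sessions)) {
        eta <- outer(lt * ability, diff_s, "+") +
          matrix(stats::rnorm(spec$n_subjects * spec$n_stimuli, 0, spec$sigma_noise),
                 spec$n_subjects, spec$n_stimuli)
        value <- if (task %in% spec$binary_tasks)
          matrix(stats::rbinom(length(eta), 1L, stats::plogis(eta)),
                 nrow(eta), ncol(eta))
        else eta
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rep(subj, times = spec$n_stimuli),
          session_id = as.character(sess),
          task = task,
          stimulus_id = rep(stims, each = spec$n_subjects),
          metric = "score",
          value = as.vector(value),
          stringsAsFactors = FALSE
        )
      }
    }
    list(scores = do.call(rbind, rows), ability = ability, difficulty = difficulty)
  })
}
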