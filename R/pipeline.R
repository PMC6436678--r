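# Pipeline surface tying the modules together over a session bundle:
# scoring every task, extracting every feature family, normalizing, and
# the cross-task analyses. The CLI is a thin wrapper over these.

#' Load the shared resources of a bundle
#'
#' @param res_dir The bundle's `resources/` directory.
#' @return List with `taxonomy`, `norms` (list of [norm_lexicon()]),
#'   `polarity`, `answer_key` (or NULL when absent).
#' @export
load_bundle_resources <- function(res_dir) {
  tax <- read_taxonomy(file.path(res_dir, "taxonomy_edges.tsv"),
                       file.path(res_dir, "taxonomy_counts.tsv"),
                       file.path(res_dir, "taxonomy_senses.tsv"))
  norm_files <- list.files(res_dir, "^lexicon_.*\\.tsv$", full.names = TRUE)
  norms <- lapply(norm_files, function(f) {
    read_norm_lexicon(f, sub("^lexicon_(.*)\\.tsv$", "\\1", basename(f)))
  })
  names(norms) <- vapply(norms, function(x) x$dimension, "")
  pol_file <- file.path(res_dir, "polarity.tsv")
  polarity <- if (file.exists(pol_file)) read_polarity_lexicon(pol_file) else NULL
  key_file <- file.path(res_dir, "answer_key.csv")
  key <- if (file.exists(key_file))
    utils::read.csv(key_file, stringsAsFactors = FALSE, colClasses = "character") else NULL
  list(taxonomy = tax, norms = norms, polarity = polarity, answer_key = key)
}

#' Score every session in a bundle
#'
#' Dispatches each session record to its task scorer: image naming
#' (Wu-Palmer vs. annotations), picture description (ICU count), fluency
#' (in/out-of-category), recall (ROUGE-1/2), vocabulary (BLEU), and
#' choice tasks (answer key). Tasks without a scorer resource are
#' skipped.
#'
#' @param bundle A [load_session_bundle()] result, or a bundle directory.
#' @param icu_threshold ICU similarity threshold (default 0.75).
#' @param tasks Optional subset of tasks to score.
#' @return Data frame `subject_id`, `session_id`, `task`, `stimulus_id`,
#'   `metric`, `value`.
#' @export
score_sessions <- function(bundle, icu_threshold = 0.75, tasks = NULL) {
  if (is.character(bundle)) bundle <- load_session_bundle(bundle)
  res <- load_bundle_resources(bundle$resources)
  tax <- res$taxonomy
  out <- list()
  emit <- function(rec, metric, value) {
    out[[length(out) + 1L]] <<- data.frame(
      subject_id = rec$subject_id, session_id = rec$session_id, task = rec$task,
      stimulus_id = rec$stimulus_id, metric = metric, value = value,
      stringsAsFactors = FALSE)
  }
  sess <- bundle$sessions
  if (!is.null(tasks)) sess <- sess[sess$task %in% tasks, , drop = FALSE]
  for (i in seq_len(nrow(sess))) {
    rec <- sess[i, ]
    rd <- bundle$resources
    switch(rec$task,
      image_naming = {
        f <- file.path(rd, paste0("annotations_", rec$stimulus_id, ".json"))
        if (file.exists(f)) {
          ann <- jsonlite::fromJSON(f)$annotations
          emit(rec, "wup", score_image_naming(rec$response, ann, tax))
        }
      },
      picture_description = {
        f <- file.path(rd, paste0("icus_", rec$stimulus_id, ".json"))
        if (file.exists(f)) {
          js <- jsonlite::fromJSON(f)
          syns <- as.list(js$manual_synonyms %||% list())
          spec <- icu_spec(js$icus, syns, threshold = icu_threshold)
          emit(rec, "icu_count",
               detect_icus(tokenize(rec$response), spec, tax)$count)
        }
      },
      fluency = {
        f <- file.path(rd, paste0("fluency_", rec$stimulus_id, ".json"))
        if (file.exists(f)) {
          js <- jsonlite::fromJSON(f)
          sc <- score_fluency(tokenize(rec$response), js$category, js$mode,
                              dictionary = js$dictionary, tax = tax)
          emit(rec, "in_category", sc[["in_category"]])
          emit(rec, "out_of_category", sc[["out_of_category"]])
        }
      },
      recall = {
        f <- file.path(rd, paste0("story_", rec$stimulus_id, ".txt"))
        if (file.exists(f)) {
          ref <- tokenize(paste(readLines(f, warn = FALSE), collapse = " "))
          cand <- tokenize(rec$response)
          emit(rec, "rouge1", rouge_score(cand, ref, 1L))
          emit(rec, "rouge2", rouge_score(cand, ref, 2L))
        }
      },
      vocabulary = {
        f <- file.path(rd, paste0("definition_", rec$stimulus_id, ".txt"))
        if (file.exists(f)) {
          ref <- tokenize(paste(readLines(f, warn = FALSE), collapse = " "))
          cand <- tokenize(rec$response)
          emit(rec, "bleu", bleu_score(cand, list(ref), max_n = 2L)$score)
        }
      },
      {
        if (!is.null(res$answer_key) && rec$stimulus_id %in% res$answer_key$stimulus_id) {
          sc <- score_choice_tasks(
            data.frame(stimulus_id = rec$stimulus_id, response = rec$response,
                       stringsAsFactors = FALSE),
            res$answer_key)
          emit(rec, "correct", sc$value)
        }
      }
    )
  }
  if (!length(out)) stop("no scorable sessions")
  do.call(rbind, out)
}

#' Extract feature families for every text session in a bundle
#'
#' Runs the lexical (richness, readability, norms, polarity), syntactic
#' (POS profile, from pre-tagged text when present), semantic (cosine,
#' taxonomy word features) and timing (alignment file when present)
#' families per session record. Family prefixes keep feature names
#' collision-free.
#'
#' @param bundle A [load_session_bundle()] result or bundle directory.
#' @param families Subset of `c("lexical", "syntactic", "semantic",
#'   "timing")`.
#' @param cosine_cutoff Cosine-distance cutoff (default 0.5).
#' @return Named list of feature vectors keyed
#'   `subject.session.task.stimulus`.
#' @export
extract_features <- function(bundle,
                             families = c("lexical", "syntactic", "semantic", "timing"),
                             cosine_cutoff = 0.5) {
  if (is.character(bundle)) bundle <- load_session_bundle(bundle)
  families <- match.arg(families, several.ok = TRUE)
  res <- load_bundle_resources(bundle$resources)
  out <- list()
  for (i in seq_len(nrow(bundle$sessions))) {
    rec <- bundle$sessions[i, ]
    if (is.na(rec$response) || !nzchar(trimws(rec$response))) next
    key <- paste(rec$subject_id, rec$session_id, rec$task, rec$stimulus_id, sep = ".")
    tc <- tryCatch(tokenize_and_count(rec$response),
                   langscore_empty_sample = function(e) NULL)
    if (is.null(tc)) next
    v <- numeric(0)
    if ("lexical" %in% families) {
      toks <- unlist(tc$transcript$utterances)
      lx <- c(richness_features(toks), readability_features(tc$counts),
              fillers_per_word = unname(tc$counts[["n_fillers"]] / tc$counts[["n_tokens"]]),
              mean_word_chars = unname(tc$counts[["mean_word_chars"]]),
              mean_word_syllables = unname(tc$counts[["mean_word_syllables"]]))
      if (length(res$norms)) lx <- c(lx, norm_features(toks, res$norms))
      if (!is.null(res$polarity)) lx <- c(lx, polarity_features(toks, res$polarity))
      names(lx) <- paste0("lex_", names(lx))
      v <- c(v, lx)
    }
    if ("syntactic" %in% families && !is.na(rec$tagged) && nzchar(rec$tagged)) {
      sx <- pos_features(count_pos_tags(read_tagged(rec$tagged)))
      names(sx) <- paste0("syn_", names(sx))
      v <- c(v, sx)
    }
    if ("semantic" %in% families) {
      se <- c(cosine_features(tc$transcript, threshold = cosine_cutoff),
              wordnet_word_features(unlist(tc$transcript$utterances), res$taxonomy))
      names(se) <- paste0("sem_", names(se))
      v <- c(v, se)
    }
    if ("timing" %in% families && !is.na(rec$alignment) && file.exists(rec$alignment)) {
      tm <- timing_features(read_alignment(rec$alignment))
      names(tm) <- paste0("tim_", names(tm))
      v <- c(v, tm)
    }
    out[[key]] <- v
  }
  out
}

#' Normalize a score table and average over sessions
#'
#' Applies per-stimulus empirical-CDF equalization within each
#' (task, metric, stimulus) group, then averages normalized scores over
#' each subject's sessions.
#'
#' @param scores Score table from [score_sessions()].
#' @return List: `normalized` (input with a `normalized` column) and
#'   `subject_scores` (subject x task.metric wide data frame of
#'   session-averaged normalized scores).
#' @export
normalize_scores <- function(scores) {
  scores$group <- paste(scores$task, scores$metric, scores$stimulus_id, sep = ".")
  norm <- cdf_normalize(scores, group_by = "group")
  norm$group <- NULL
  agg <- stats::aggregate(normalized ~ subject_id + task + metric, data = norm, FUN = mean)
  agg$col <- paste(agg$task, agg$metric, sep = ".")
  wide <- stats::reshape(agg[c("subject_id", "col", "normalized")],
                         idvar = "subject_id", timevar = "col", direction = "wide")
  names(wide) <- sub("^normalized\\.", "", names(wide))
  rownames(wide) <- NULL
  list(normalized = norm, subject_scores = wide)
}

#' Cross-task analysis of a subject-score table
#'
#' Computes the masked cross-task correlation table, a PCA of the score
#' metrics, and (when at least two tasks are present) a CCA between the
#' first task's metrics and the remaining tasks' metrics.
#'
#' @param subject_scores Wide data frame from [normalize_scores()]
#'   (`subject_id` + `task.metric` columns).
#' @param cca_k Number of canonical embeddings (capped by the view
#'   dimensions).
#' @param ridge CCA regularization.
#' @param alpha Correlation significance level.
#' @return List: `correlations`, `pca`, `cca` (NULL when inapplicable).
#' @export
analyze_scores <- function(subject_scores, cca_k = 20L, ridge = 1e-3, alpha = 0.05) {
  X <- as.matrix(subject_scores[setdiff(names(subject_scores), "subject_id")])
  task_of <- sub("\\..*$", "", colnames(X))
  corrs <- cross_task_correlations(X, stats::setNames(task_of, colnames(X)),
                                   alpha = alpha)
  keep <- stats::complete.cases(X)
  Xc <- X[keep, , drop = FALSE]
  nonconst <- apply(Xc, 2L, stats::sd) > 0
  pca <- if (sum(nonconst) >= 2L)
    pca_scores(Xc[, nonconst, drop = FALSE], k = min(2L, sum(nonconst))) else NULL
  cca <- NULL
  tasks <- unique(task_of)
  if (length(tasks) >= 2L) {
    v1 <- Xc[, task_of == tasks[1] & nonconst, drop = FALSE]
    v2 <- Xc[, task_of != tasks[1] & nonconst, drop = FALSE]
    if (ncol(v1) >= 1L && ncol(v2) >= 1L && nrow(Xc) >= 3L)
      cca <- cca_fit(v1, v2, k = cca_k, ridge = ridge)
  }
  list(correlations = corrs, pca = pca, cca = cca)
}
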