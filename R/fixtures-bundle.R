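# A complete on-disk fixture bundle: taxonomy, lexicons, per-stimulus
# resources, and a cohort of synthetic session records in the exact file
# formats the readers consume. The whole pipeline (simulate -> extract ->
# score -> normalize -> analyze) runs offline on a bundle.

#' Generate a synthetic session bundle on disk
#'
#' Creates `sessions.jsonl`, an `alignments/` directory and a
#' `resources/` directory (taxonomy TSVs, seven norm lexicons, a polarity
#' lexicon, ICU lists, stories, reference definitions, fluency
#' dictionaries, image annotations, an answer key). Each subject has a
#' latent quality in \[0, 1\] that monotonically drives response quality
#' across tasks; the generation is bit-reproducible per seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_subjects Number of subjects (default 12).
#' @param n_stimuli Stimuli per task (default 3).
#' @param n_concepts,vocabulary_size Taxonomy size parameters.
#' @return Invisibly, a list with the bundle `dir`, the subject `quality`
#'   vector and the generated `taxonomy`.
#' @export
gen_fixture_bundle <- function(dir, seed = 0L, n_subjects = 12L, n_stimuli = 3L,
                               n_concepts = 40L, vocabulary_size = 80L) {
  res_dir <- file.path(dir, "resources")
  aln_dir <- file.path(dir, "alignments")
  for (d in c(dir, res_dir, aln_dir)) dir.create(d, showWarnings = FALSE, recursive = TRUE)

  tax <- gen_taxonomy(n_concepts, branching = 3L, vocabulary_size = vocabulary_size,
                      seed = seed)
  write_taxonomy(tax,
                 file.path(res_dir, "taxonomy_edges.tsv"),
                 file.path(res_dir, "taxonomy_counts.tsv"),
                 file.path(res_dir, "taxonomy_senses.tsv"))
  vocab <- names(tax$senses)
  lex <- gen_lexicons(vocab, seed = seed, coverage = 0.8)
  for (d in names(lex$norms)) {
    e <- lex$norms[[d]]$entries
    writeLines(paste(names(e), format(e, trim = TRUE), sep = "\t"),
               file.path(res_dir, paste0("lexicon_", d, ".tsv")))
  }
  pe <- lex$polarity$entries
  writeLines(paste(names(pe), unname(pe), sep = "\t"),
             file.path(res_dir, "polarity.tsv"))

  bundle <- with_seed(derive_seed(seed, "bundle"), {
    subj <- sprintf("s%03d", seq_len(n_subjects))
    quality <- stats::setNames(round(stats::runif(n_subjects), 3), subj)

    # per-stimulus resources -------------------------------------------------
    pd_stims <- sprintf("pd%02d", seq_len(n_stimuli))
    icu_lists <- list()
    for (st in pd_stims) {
      single <- sample(vocab, 4L)
      pair <- paste(sample(setdiff(vocab, single), 2L), collapse = " ")
      icus <- c(single, pair)
      icu_lists[[st]] <- icus
      jsonlite::write_json(list(icus = icus, manual_synonyms = stats::setNames(list(), character(0)),
                                threshold = 0.75),
                           file.path(res_dir, paste0("icus_", st, ".json")),
                           auto_unbox = TRUE)
    }
    sr_stims <- sprintf("sr%02d", seq_len(n_stimuli))
    stories <- list()
    for (st in sr_stims) {
      stories[[st]] <- sample(vocab, 24L, replace = TRUE)
      writeLines(paste(stories[[st]], collapse = " "),
                 file.path(res_dir, paste0("story_", st, ".txt")))
    }
    fl_stims <- sprintf("fl%02d", seq_len(n_stimuli))
    fl_res <- list()
    for (st in fl_stims) {
      cat_concept <- sample(setdiff(tax$concepts, tax$root), 1L)
      members <- Filter(function(w) any(vapply(tax$senses[[w]],
                          function(s) cat_concept %in% tax_ancestors(tax, s), TRUE)),
                        vocab)
      dict <- if (length(members) >= 4L) members[1:4] else sample(vocab, 4L)
      fl_res[[st]] <- list(mode = "semantic", category = cat_concept, dictionary = dict)
      jsonlite::write_json(fl_res[[st]],
                           file.path(res_dir, paste0("fluency_", st, ".json")),
                           auto_unbox = TRUE)
    }
    vc_stims <- sprintf("vc%02d", seq_len(n_stimuli))
    defs <- list()
    for (st in vc_stims) {
      defs[[st]] <- sample(vocab, 10L, replace = TRUE)
      writeLines(paste(defs[[st]], collapse = " "),
                 file.path(res_dir, paste0("definition_", st, ".txt")))
    }
    im_stims <- sprintf("im%02d", seq_len(n_stimuli))
    annots <- list()
    for (st in im_stims) {
      annots[[st]] <- sample(vocab, 3L)
      jsonlite::write_json(list(annotations = annots[[st]]),
                           file.path(res_dir, paste0("annotations_", st, ".json")),
                           auto_unbox = TRUE)
    }
    wg_stims <- sprintf("wg%02d", seq_len(n_stimuli))
    key <- data.frame(stimulus_id = wg_stims, type = "choice",
                      answer = sample(c("a", "b"), n_stimuli, replace = TRUE),
                      stringsAsFactors = FALSE)
    utils::write.csv(key, file.path(res_dir, "answer_key.csv"), row.names = FALSE)

    # session records ---------------------------------------------------------
    recs <- list()
    add <- function(subject, task, stim, response, alignment = NA, tagged = NA) {
      recs[[length(recs) + 1L]] <<- data.frame(
        subject_id = subject, session_id = "1", task = task, stimulus_id = stim,
        response = response, alignment = alignment, tagged = tagged,
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(subj)) {
      q <- quality[[i]]
      sseed <- derive_seed(seed, paste0("subj", i))
      for (st in pd_stims) {
        g <- gen_transcript("picture_description", list(icus = icu_lists[[st]]),
                            quality = q, seed = derive_seed(sseed, st))
        aln <- file.path(aln_dir, paste0(subj[i], "_", st, ".txt"))
        utils::write.table(g$alignment, aln, row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
        add(subj[i], "picture_description", st,
            paste(unlist(g$transcript$utterances), collapse = " "),
            alignment = aln, tagged = g$tagged)
      }
      for (st in sr_stims) {
        g <- gen_transcript("recall", list(story = stories[[st]]),
                            quality = q, seed = derive_seed(sseed, st))
        add(subj[i], "recall", st, paste(unlist(g$transcript$utterances), collapse = " "))
      }
      for (st in fl_stims) {
        g <- gen_transcript("fluency", list(dictionary = fl_res[[st]]$dictionary),
                            quality = q, seed = derive_seed(sseed, st))
        add(subj[i], "fluency", st, paste(unlist(g$transcript$utterances), collapse = " "))
      }
      for (st in vc_stims) {
        g <- gen_transcript("vocabulary", list(definition = defs[[st]]),
                            quality = q, seed = derive_seed(sseed, st))
        add(subj[i], "vocabulary", st, paste(unlist(g$transcript$utterances), collapse = " "))
      }
      for (k in seq_along(wg_stims)) {
        correct <- stats::runif(1) < 0.25 + 0.7 * q
        resp <- if (correct) key$answer[k] else setdiff(c("a", "b"), key$answer[k])
        add(subj[i], "winograd", wg_stims[k], resp)
      }
    }
    sessions <- do.call(rbind, recs)
    write_sessions(sessions, file.path(dir, "sessions.jsonl"))
    list(dir = dir, quality = quality, taxonomy = tax)
  })
  invisible(bundle)
}
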