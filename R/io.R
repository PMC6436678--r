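# Interchange I/O: JSONL session bundles (fail-soft ingestion with an
# error report), feature tables (wide/long CSV, empty-cell missing
# convention), and score tables.

task_inventory <- function() {
  c("image_naming", "picture_description", "fluency", "recall",
    "vocabulary", "winograd", "stroop", "gds")
}

#' Write session records as JSONL
#'
#' @param records Data frame with columns `subject_id`, `session_id`,
#'   `task`, `stimulus_id`, `response` (and optionally `alignment`,
#'   `tagged` paths).
#' @param path Output file (one JSON object per line).
#' @return Invisibly, `path`.
#' @export
write_sessions <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    jsonlite::toJSON(as.list(records[i, , drop = FALSE]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Load a session bundle
#'
#' A bundle is a directory with a `sessions.jsonl` file (one session
#' record per line) and a `resources/` subdirectory (taxonomy, lexicons,
#' ICU lists, stories, dictionaries, answer keys). Ingestion is
#' fail-soft: malformed records are collected into an error report and
#' valid records processed; only a bundle with no valid record at all is
#' rejected.
#'
#' @param path Bundle directory.
#' @return List of class `session_bundle`: `sessions` (data frame),
#'   `resources` (resource directory path), `errors` (character vector of
#'   skipped-record reports).
#' @export
load_session_bundle <- function(path) {
  sess_file <- file.path(path, "sessions.jsonl")
  if (!file.exists(sess_file)) stop("no sessions.jsonl under ", path)
  lines <- readLines(sess_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  required <- c("subject_id", "session_id", "task", "stimulus_id")
  recs <- list(); errors <- character(0)
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec)) { errors <- c(errors, sprintf("line %d: unparseable JSON", i)); next }
    missing <- required[!vapply(required, function(f) !is.null(rec[[f]]) && nzchar(as.character(rec[[f]])), TRUE)]
    if (length(missing)) {
      errors <- c(errors, sprintf("line %d: missing %s", i, paste(missing, collapse = ", ")))
      next
    }
    if (!rec$task %in% task_inventory()) {
      errors <- c(errors, sprintf("line %d: unknown task '%s' (known: %s)", i,
                                  rec$task, paste(task_inventory(), collapse = ", ")))
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      subject_id = rec$subject_id, session_id = as.character(rec$session_id),
      task = rec$task, stimulus_id = rec$stimulus_id,
      response = rec$response %||% NA_character_,
      alignment = rec$alignment %||% NA_character_,
      tagged = rec$tagged %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(recs)) stop("no valid session records in ", sess_file)
  structure(list(sessions = do.call(rbind, recs),
                 resources = file.path(path, "resources"),
                 errors = errors),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d sessions (%d skipped), resources at %s\n",
              nrow(x$sessions), length(x$errors), x$resources))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' Missing features are written as empty cells; column order is the
#' stable union of feature names in first-seen order, so identical inputs
#' produce identical files.
#'
#' @param vectors Named list of feature vectors (names are record ids).
#' @param path Output CSV path.
#' @param layout `"wide"` (one row per record) or `"long"`
#'   (`id`, `feature`, `value`).
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(vectors, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(is.list(vectors), !is.null(names(vectors)))
  feats <- unique(unlist(lapply(vectors, names)))
  if (layout == "wide") {
    M <- do.call(rbind, lapply(vectors, function(v) v[feats]))
    df <- data.frame(id = names(vectors), M, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    df <- do.call(rbind, lapply(names(vectors), function(id) {
      v <- vectors[[id]]
      data.frame(id = id, feature = names(v), value = unname(v),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return Named list of feature vectors.
#' @export
read_feature_table <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    ids <- df$id
    M <- as.matrix(df[setdiff(names(df), "id")])
    stats::setNames(lapply(seq_along(ids), function(i) {
      v <- suppressWarnings(as.numeric(M[i, ]))
      stats::setNames(v, colnames(M))
    }), ids)
  } else {
    split_df <- split(df, df$id)
    lapply(split_df, function(d) stats::setNames(as.numeric(d$value), d$feature))
  }
}

#' Read a flat key=value config file
#'
#' Recognized keys: `icu_threshold` (default 0.75), `cosine_cutoff`
#' (0.5), `cca_k` (20), `ridge` (1e-3), `seed` (0). Unknown keys are kept
#' as strings.
#'
#' @param path Config file; `NULL` returns the defaults.
#' @return Named list of settings.
#' @export
read_config <- function(path = NULL) {
  cfg <- list(icu_threshold = 0.75, cosine_cutoff = 0.5, cca_k = 20L,
              ridge = 1e-3, seed = 0L)
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE) & !grepl("^\\s*#", lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (is.na(num)) val else num
  }
  cfg
}
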