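# Timing feature family: pause and duration statistics from word-level
# alignment timestamps. Pauses are inter-word gaps only; a gap qualifies as
# a pause when it exceeds 150 ms, as short when strictly inside
# (150 ms, 400 ms), and as long when >= 400 ms (the 400 ms boundary is
# assigned to "long"). Leading/trailing file silence is not a pause.

#' Read a word-level alignment file
#'
#' @param path File with one `word onset_s offset_s` per line
#'   (whitespace-delimited, seconds).
#' @return Data frame with columns `word`, `onset_s`, `offset_s`.
#' @export
read_alignment <- function(path) {
  tb <- utils::read.table(path, header = FALSE,
                          col.names = c("word", "onset_s", "offset_s"),
                          colClasses = c("character", "numeric", "numeric"))
  tb
}

#' Pause and duration features from aligned segments
#'
#' @param segments Data frame with numeric `onset_s`, `offset_s` columns
#'   (and optionally `word`), time-ordered and non-overlapping, all times
#'   >= 0.
#' @param total_duration_s Total sample duration; must be >= the last
#'   offset. Defaults to the last offset.
#' @return Named numeric vector: `total_duration`, `active_ratio`
#'   (speech time / total), `pause_mean`, `short_pause_mean`,
#'   `long_pause_mean` (NA when the corresponding set is empty),
#'   `pause_ratio` (count of pauses / count of segments) and
#'   `pause_duration_ratio` (summed pause time / summed speech time).
#' @export
timing_features <- function(segments, total_duration_s = NULL) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L,
            all(c("onset_s", "offset_s") %in% names(segments)))
  on <- segments$onset_s; off <- segments$offset_s
  if (any(off < on) || any(on < 0)) stop("segments must satisfy 0 <= onset <= offset")
  if (nrow(segments) > 1L && any(diff(on) < 0 | utils::head(off, -1L) > utils::tail(on, -1L)))
    stop("segments must be time-ordered and non-overlapping")
  total <- total_duration_s %||% off[length(off)]
  if (total < off[length(off)]) stop("total_duration_s is shorter than the last offset")
  # alignments carry millisecond precision; rounding keeps the 150/400 ms
  # band boundaries exact under floating-point subtraction
  gaps <- if (nrow(segments) > 1L)
    round(utils::tail(on, -1L) - utils::head(off, -1L), 6L) else numeric(0)
  pauses <- gaps[gaps > 0.150]
  short <- gaps[gaps > 0.150 & gaps < 0.400]
  long <- gaps[gaps >= 0.400]
  active <- sum(off - on)
  feature_vector(
    total_duration = total,
    active_ratio = active / total,
    pause_mean = if (length(pauses)) mean(pauses) else NA_real_,
    short_pause_mean = if (length(short)) mean(short) else NA_real_,
    long_pause_mean = if (length(long)) mean(long) else NA_real_,
    pause_ratio = length(pauses) / nrow(segments),
    pause_duration_ratio = if (active > 0) sum(pauses) / active else NA_real_
  )
}
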