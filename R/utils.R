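#' @keywords internal
"_PACKAGE"

# Run expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Derive an independent sub-stream seed from a master seed and a stream label,
# so one global seed fans out to per-generator streams deterministically.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h %% 104729) %% 2147483647)
}

# Classed condition for empty / whitespace-only samples: callers can
# distinguish "nothing to analyze" from programming errors.
empty_sample_error <- function(msg = "empty or whitespace-only sample") {
  structure(
    class = c("langscore_empty_sample", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

is_missing_val <- function(x) is.na(x)

# A feature vector is a named numeric vector; NA marks "undefined here"
# (never NaN, never Inf).
feature_vector <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)), all(nzchar(names(v))))
  v[!is.finite(v)] <- NA_real_
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Safe ratio: NA on zero denominator (never Inf/NaN); 0/pos stays 0.
safe_ratio <- function(num, den) {
  if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
  num / den
}
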