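# Lexical feature family: vocabulary richness, readability, psycholinguistic
# norms and polarity. Undefined features are NA, never NaN/Inf.

#' Vocabulary-richness features
#'
#' Computes the type-token ratio, moving-average TTR over sliding windows,
#' the Brunet index `BI = N^(U^-0.165)` and the Honore statistic
#' `HS = 100 * ln(N) / (1 - N1/U)`, where `N` is the token count, `U` the
#' type count and `N1` the number of hapax legomena. `HS` is undefined
#' (NA) when every type is a hapax (`N1 = U`); `MATTR_w` is undefined when
#' the sample is shorter than the window.
#'
#' @param tokens Character vector of (lowercased) tokens.
#' @param windows Integer MATTR window sizes.
#' @return Named numeric feature vector (`ttr`, `mattr_10` ...,
#'   `brunet_index`, `honore_statistic`).
#' @export
richness_features <- function(tokens, windows = c(10L, 20L, 30L, 40L, 50L)) {
  nm <- c("ttr", paste0("mattr_", windows), "brunet_index", "honore_statistic")
  if (length(tokens) == 0L)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  N <- length(tokens)
  tab <- table(tokens)
  U <- length(tab)
  N1 <- sum(tab == 1L)
  out <- c(ttr = U / N)
  for (w in windows) {
    out[paste0("mattr_", w)] <- if (N < w) NA_real_ else {
      mean(vapply(seq_len(N - w + 1L),
                  function(i) length(unique(tokens[i:(i + w - 1L)])) / w, 1.0))
    }
  }
  out["brunet_index"] <- N^(U^-0.165)
  out["honore_statistic"] <- if (N1 == U) NA_real_ else 100 * log(N) / (1 - N1 / U)
  feature_vector(out)
}

#' Readability features (Flesch family)
#'
#' Flesch reading ease
#' `F = 206.835 - 1.015*(words/sentences) - 84.6*(syllables/words)` and the
#' Flesch-Kincaid grade level
#' `FK = 0.39*(words/sentences) + 11.8*(syllables/words) - 15.59`.
#' `fk_printed_constant = TRUE` flips the final FK constant to `+15.59`, a
#' variant that circulates in some write-ups of the grade-level formula.
#'
#' @param counts Surface counts as returned by [tokenize_and_count()]
#'   (`n_tokens`, `n_sentences`, `n_syllables` are used).
#' @param fk_printed_constant Use `+15.59` instead of the standard
#'   `-15.59` in the grade-level formula.
#' @return Named numeric vector `c(flesch, flesch_kincaid)`; NA when there
#'   are no words or no sentences.
#' @export
readability_features <- function(counts, fk_printed_constant = FALSE) {
  w <- counts[["n_tokens"]]; s <- counts[["n_sentences"]]; y <- counts[["n_syllables"]]
  if (is.na(w) || is.na(s) || w < 1 || s < 1)
    return(feature_vector(flesch = NA_real_, flesch_kincaid = NA_real_))
  wps <- w / s; spw <- y / w
  k <- if (fk_printed_constant) 15.59 else -15.59
  feature_vector(
    flesch = 206.835 - 1.015 * wps - 84.6 * spw,
    flesch_kincaid = 0.39 * wps + 11.8 * spw + k
  )
}

#' Construct a psycholinguistic norm lexicon
#'
#' @param dimension One of `"frequency"`, `"aoa"`, `"imageability"`,
#'   `"familiarity"`, `"arousal"`, `"dominance"`, `"valence"`.
#' @param entries Named numeric vector, word -> norm value (finite).
#' @return Object of class `norm_lexicon`.
#' @export
norm_lexicon <- function(dimension, entries) {
  dimension <- match.arg(dimension, c("frequency", "aoa", "imageability",
                                      "familiarity", "arousal", "dominance", "valence"))
  stopifnot(is.numeric(entries), !is.null(names(entries)), all(is.finite(entries)))
  names(entries) <- tolower(names(entries))
  structure(list(dimension = dimension, entries = entries), class = "norm_lexicon")
}

#' Norm-based lexical features
#'
#' For each norm dimension: mean and standard deviation of the norm over
#' tokens found in that lexicon, plus the coverage (fraction of tokens
#' found). A dimension with no covered token is NA (coverage 0).
#'
#' @param tokens Character token vector.
#' @param lexicons List of [norm_lexicon()] objects.
#' @return Named numeric vector (`<dim>_mean`, `<dim>_sd`, `<dim>_coverage`).
#' @export
norm_features <- function(tokens, lexicons) {
  stopifnot(length(lexicons) >= 1L)
  out <- numeric(0)
  for (lx in lexicons) {
    stopifnot(inherits(lx, "norm_lexicon"))
    d <- lx$dimension
    vals <- lx$entries[tolower(tokens)]
    vals <- vals[!is.na(vals)]
    cov <- if (length(tokens)) length(vals) / length(tokens) else 0
    out[paste0(d, "_mean")] <- if (length(vals)) mean(vals) else NA_real_
    out[paste0(d, "_sd")] <- if (length(vals) >= 2L) stats::sd(vals) else if (length(vals) == 1L) 0 else NA_real_
    out[paste0(d, "_coverage")] <- cov
  }
  feature_vector(out)
}

#' Construct a word-polarity lexicon
#'
#' Categorical polarity labels with an explicit numeric coding. The default
#' four-level coding maps strong/weak negative to -2/-1 and weak/strong
#' positive to +1/+2; a five-level coding with a neutral 0 is also common.
#' Every category occurring in `entries` must have a numeric mapping.
#'
#' @param entries Named character vector, word -> category.
#' @param numeric_map Named numeric vector, category -> value.
#' @return Object of class `polarity_lexicon`.
#' @export
polarity_lexicon <- function(entries,
                             numeric_map = c("strong negative" = -2, "weak negative" = -1,
                                             "weak positive" = 1, "strong positive" = 2)) {
  stopifnot(is.character(entries), !is.null(names(entries)))
  names(entries) <- tolower(names(entries))
  missing_cat <- setdiff(unique(entries), names(numeric_map))
  if (length(missing_cat))
    stop("polarity categories without a numeric mapping: ",
         paste(missing_cat, collapse = ", "))
  structure(list(entries = entries, numeric_map = numeric_map),
            class = "polarity_lexicon")
}

#' Polarity features
#'
#' Mean and standard deviation of the numerically-coded polarity over
#' in-lexicon tokens, plus per-category proportions (which sum to 1 over
#' covered tokens).
#'
#' @param tokens Character token vector.
#' @param lexicon A [polarity_lexicon()].
#' @return Named numeric vector (`polarity_mean`, `polarity_sd`,
#'   `polarity_coverage`, `polarity_prop_<category>`).
#' @export
polarity_features <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "polarity_lexicon"))
  cats <- lexicon$entries[tolower(tokens)]
  cats <- cats[!is.na(cats)]
  vals <- lexicon$numeric_map[cats]
  cov <- if (length(tokens)) length(cats) / length(tokens) else 0
  out <- c(
    polarity_mean = if (length(vals)) mean(vals) else NA_real_,
    polarity_sd = if (length(vals) >= 2L) stats::sd(vals) else if (length(vals) == 1L) 0 else NA_real_,
    polarity_coverage = cov
  )
  for (cat in names(lexicon$numeric_map)) {
    key <- paste0("polarity_prop_", gsub("\\s+", "_", cat))
    out[key] <- if (length(cats)) mean(cats == cat) else NA_real_
  }
  feature_vector(out)
}

#' Read a norm lexicon from TSV
#'
#' @param path TSV file with lines `word<TAB>value`.
#' @param dimension Norm dimension name (see [norm_lexicon()]).
#' @return A [norm_lexicon()].
#' @export
read_norm_lexicon <- function(path, dimension) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"), quote = "")
  norm_lexicon(dimension, stats::setNames(tb[[2]], tb[[1]]))
}

#' Read a polarity lexicon from TSV
#'
#' @param path TSV file with lines `word<TAB>category`.
#' @param numeric_map Category -> numeric value map (see
#'   [polarity_lexicon()]).
#' @return A [polarity_lexicon()].
#' @export
read_polarity_lexicon <- function(path, numeric_map = NULL) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  entries <- stats::setNames(tb[[2]], tb[[1]])
  if (is.null(numeric_map)) polarity_lexicon(entries)
  else polarity_lexicon(entries, numeric_map)
}
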