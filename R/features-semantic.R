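# Semantic feature family: pairwise cosine distance between bag-of-types
# utterance embeddings, and taxonomy-derived word specificity/ambiguity.

#' Utterance-level cosine-distance features
#'
#' Each utterance is embedded as a binary bag-of-types vector over the
#' transcript vocabulary; for every unordered pair of utterances the cosine
#' distance `d = 1 - cos` is computed. Features: mean distance, minimum
#' distance, and the fraction of pairs with `d <= threshold` (the "cosine
#' cutoff"). Utterances with no vocabulary are excluded from pairing;
#' fewer than two pairable utterances yields all-NA.
#'
#' @param x A `transcript` or a list of token vectors.
#' @param threshold Cutoff distance (default 0.5).
#' @return Named numeric vector `c(cos_dist_mean, cos_dist_min,
#'   cos_cutoff_prop)`.
#' @export
cosine_features <- function(x, threshold = 0.5) {
  utts <- if (inherits(x, "transcript")) x$utterances else x
  utts <- lapply(utts, function(u) unique(tolower(u)))
  utts <- utts[vapply(utts, length, 1L) > 0L]
  if (length(utts) < 2L)
    return(feature_vector(cos_dist_mean = NA_real_, cos_dist_min = NA_real_,
                          cos_cutoff_prop = NA_real_))
  vocab <- sort(unique(unlist(utts)))
  M <- vapply(utts, function(u) as.numeric(vocab %in% u),
              numeric(length(vocab)))
  M <- matrix(M, nrow = length(vocab))
  pairs <- utils::combn(ncol(M), 2L)
  d <- apply(pairs, 2L, function(ij) {
    a <- M[, ij[1]]; b <- M[, ij[2]]
    1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  feature_vector(cos_dist_mean = mean(d), cos_dist_min = min(d),
                 cos_cutoff_prop = mean(d <= threshold))
}

#' Taxonomy-derived word specificity and ambiguity
#'
#' Specificity is the depth of a word's most-frequent sense (deeper =
#' more specific); ambiguity is its number of senses. Means are taken over
#' in-taxonomy tokens; both are NA when no token is covered.
#'
#' @param tokens Character token vector.
#' @param tax A [taxonomy()].
#' @return Named numeric vector `c(specificity_mean, ambiguity_mean,
#'   taxonomy_coverage)`.
#' @export
wordnet_word_features <- function(tokens, tax) {
  stopifnot(inherits(tax, "taxonomy"))
  senses <- lapply(tokens, function(w) word_senses(tax, w, "all"))
  covered <- vapply(senses, length, 1L) > 0L
  cov <- if (length(tokens)) mean(covered) else 0
  if (!any(covered))
    return(feature_vector(specificity_mean = NA_real_, ambiguity_mean = NA_real_,
                          taxonomy_coverage = cov))
  depths <- vapply(senses[covered], function(s) as.numeric(tax$depth[[s[1]]]), 1.0)
  feature_vector(
    specificity_mean = mean(depths),
    ambiguity_mean = mean(vapply(senses[covered], length, 1L)),
    taxonomy_coverage = cov
  )
}
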