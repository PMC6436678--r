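# Score normalization: per-stimulus empirical-CDF equalization (removes
# stimulus difficulty), simplicity-weighted averaging for binary tasks,
# and KL divergence between per-stimulus score distributions.

#' Per-stimulus empirical-CDF score equalization
#'
#' Within each stimulus group, a raw score `x` maps to
#' `F(x) = (# scores <= x) / n`, so each stimulus's scores become
#' (discretely) uniform on (0, 1\] and stimulus difficulty is removed.
#' Tied raw values receive identical normalized values, and the transform
#' is invariant to any strictly increasing rescaling of the raw scores.
#' Singleton groups normalize to 1 with a warning.
#'
#' @param scores Data frame with at least `stimulus_id` and `value`
#'   columns (any additional identifier columns are carried through).
#' @param group_by Grouping column name (default `"stimulus_id"`).
#' @return The input data frame with a `normalized` column added.
#' @export
cdf_normalize <- function(scores, group_by = "stimulus_id") {
  stopifnot(is.data.frame(scores), "value" %in% names(scores),
            group_by %in% names(scores))
  out <- scores
  out$normalized <- NA_real_
  for (g in unique(scores[[group_by]])) {
    idx <- which(scores[[group_by]] == g)
    v <- scores$value[idx]
    if (length(v) == 1L) {
      warning("singleton group '", g, "' normalized to 1")
      out$normalized[idx] <- 1
    } else {
      out$normalized[idx] <- vapply(v, function(x) mean(v <= x), 1.0)
    }
  }
  out
}

#' Per-stimulus simplicity weights
#'
#' A binary question's simplicity is the observed rate of correct
#' responses to it, computed over all available responses.
#'
#' @param scores Data frame with `stimulus_id` and 0/1 `value` columns.
#' @return Data frame `stimulus_id`, `weight`.
#' @export
question_weights <- function(scores) {
  stopifnot(all(scores$value %in% c(0, 1)))
  agg <- stats::aggregate(value ~ stimulus_id, data = scores, FUN = mean)
  data.frame(stimulus_id = agg$stimulus_id, weight = agg$value,
             stringsAsFactors = FALSE)
}

#' Simplicity-weighted average of binary answers
#'
#' `score = sum(w_j x_j) / sum(w_j)` over answered items, so missing an
#' easy (high-simplicity) question degrades the score more than missing a
#' hard one.
#'
#' @param answers Named 0/1 vector (names: stimulus ids).
#' @param weights Data frame from [question_weights()], or a named numeric
#'   vector of weights in \[0, 1\].
#' @return Numeric score in \[0, 1\]; NA when the summed weight is 0.
#' @export
weighted_question_average <- function(answers, weights) {
  if (is.data.frame(weights))
    weights <- stats::setNames(weights$weight, weights$stimulus_id)
  stopifnot(all(answers %in% c(0, 1)), !is.null(names(answers)))
  miss <- setdiff(names(answers), names(weights))
  if (length(miss)) stop("no weight for stimuli: ", paste(miss, collapse = ", "))
  w <- weights[names(answers)]
  if (sum(w) == 0) return(NA_real_)
  sum(w * answers) / sum(w)
}

#' Kullback-Leibler divergence between two score samples
#'
#' Both samples are histogrammed on a shared integer-bin support, smoothed
#' additively (`eps = 1e-6`) and renormalized; the divergence
#' `KL(P || Q) = sum p log(p/q)` is nonnegative, finite under smoothing,
#' and asymmetric.
#'
#' @param p_scores,q_scores Nonempty numeric vectors.
#' @param breaks Optional histogram breaks; defaults to unit-width integer
#'   bins spanning both samples.
#' @param eps Additive smoothing constant.
#' @return Nonnegative numeric divergence (nats).
#' @export
kl_divergence <- function(p_scores, q_scores, breaks = NULL, eps = 1e-6) {
  stopifnot(length(p_scores) >= 1L, length(q_scores) >= 1L)
  if (is.null(breaks)) {
    # integer-centered unit bins so each integer score gets its own bin
    lo <- floor(min(p_scores, q_scores)); hi <- ceiling(max(p_scores, q_scores))
    breaks <- seq(lo - 0.5, hi + 0.5, by = 1)
  }
  bin_counts <- function(x) {
    x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE),
             nbins = length(breaks) - 1L)
  }
  hp <- bin_counts(p_scores)
  hq <- bin_counts(q_scores)
  p <- (hp + eps) / sum(hp + eps)
  q <- (hq + eps) / sum(hq + eps)
  sum(p * log(p / q))
}

#' Pairwise KL-divergence matrix, linearly rescaled for display
#'
#' @param samples Named list of numeric score vectors (e.g., in-category
#'   fluency counts per stimulus).
#' @param rescale Linearly map the off-diagonal values onto \[0, 1\]
#'   (display convention; diagonal stays 0).
#' @return Square matrix of KL(P_i || P_j) values.
#' @export
kl_matrix <- function(samples, rescale = TRUE) {
  k <- length(samples)
  stopifnot(k >= 2L)
  M <- matrix(0, k, k, dimnames = list(names(samples), names(samples)))
  lo <- floor(min(unlist(samples))); hi <- ceiling(max(unlist(samples)))
  breaks <- seq(lo - 0.5, hi + 0.5, by = 1)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) M[i, j] <- kl_divergence(samples[[i]], samples[[j]], breaks)
  }
  if (rescale) {
    off <- M[row(M) != col(M)]
    rng <- range(off)
    if (diff(rng) > 0) M[row(M) != col(M)] <- (off - rng[1]) / diff(rng)
  }
  M
}
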