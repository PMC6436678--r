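# Maximum-weight bipartite assignment for multi-word ICU matching.
# Exhaustive enumeration for small problems; O(n^3) Hungarian otherwise.
# A greedy variant is provided for comparison only — best-first local
# pairing is demonstrably suboptimal when the best local choice strands a
# later word.

#' Maximum-weight bipartite assignment
#'
#' Given an `m x n` weight matrix (rows: ICU words, columns: window words,
#' `m >= n`), finds the injective column-to-row pairing maximizing total
#' weight.
#'
#' @param weights Numeric `m x n` matrix, `m >= n >= 1`; similarity use
#'   puts entries in \[0, 1\] but any finite weights are accepted.
#' @param method `"auto"` (exhaustive up to n = 8, Hungarian above),
#'   `"exhaustive"`, `"hungarian"`, or `"greedy"` (best-first local
#'   pairing; not guaranteed optimal — provided for comparison).
#' @return List with `pairs` (integer vector: `pairs[j]` is the row
#'   assigned to column `j`) and `total` (summed weight).
#' @export
max_weight_assignment <- function(weights,
                                  method = c("auto", "exhaustive", "hungarian", "greedy")) {
  method <- match.arg(method)
  if (!is.matrix(weights) || length(weights) == 0L)
    stop("weights must be a nonempty matrix")
  if (!all(is.finite(weights))) stop("weights must be finite")
  m <- nrow(weights); n <- ncol(weights)
  if (m < n) stop("expected m >= n (at least as many rows as columns)")
  if (method == "auto") method <- if (n <= 8L) "exhaustive" else "hungarian"
  switch(method,
    exhaustive = assign_exhaustive(weights),
    hungarian = assign_hungarian(weights),
    greedy = assign_greedy(weights)
  )
}

assign_exhaustive <- function(w) {
  m <- nrow(w); n <- ncol(w)
  best <- -Inf; best_pairs <- integer(0)
  rec <- function(j, used, pairs, acc) {
    if (j > n) {
      if (acc > best) { best <<- acc; best_pairs <<- pairs }
      return(invisible())
    }
    for (i in seq_len(m)) {
      if (!used[i]) {
        used[i] <- TRUE
        rec(j + 1L, used, c(pairs, i), acc + w[i, j])
        used[i] <- FALSE
      }
    }
  }
  rec(1L, logical(m), integer(0), 0)
  list(pairs = best_pairs, total = best)
}

assign_greedy <- function(w) {
  m <- nrow(w); n <- ncol(w)
  pairs <- integer(n)
  ww <- w
  total <- 0
  for (k in seq_len(n)) {
    idx <- which(ww == max(ww), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    pairs[idx[2]] <- idx[1]
    total <- total + w[idx[1], idx[2]]
    ww[idx[1], ] <- -Inf
    ww[, idx[2]] <- -Inf
  }
  list(pairs = pairs, total = total)
}

# Shortest-augmenting-path Hungarian algorithm on the square-padded cost
# matrix cost = max(w) - w (padding columns cost 0, so real columns always
# receive real rows optimally).
assign_hungarian <- function(w) {
  m <- nrow(w); n <- ncol(w)
  N <- m  # pad columns up to m so every row can absorb a dummy column
  cost <- matrix(0, N, N)
  cost[, seq_len(n)] <- max(w) - w
  u <- numeric(N)          # row potentials
  v <- numeric(N + 1L)     # column potentials, index 1 = virtual column
  p <- integer(N + 1L)     # p[j]: row matched to (shifted) column j; 0 = free
  way <- integer(N + 1L)
  for (i in seq_len(N)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, N + 1L)
    used <- logical(N + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(N) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(N + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  pairs <- integer(n)
  for (j in seq_len(N) + 1L) {
    col <- j - 1L
    if (col <= n) pairs[col] <- p[j]
  }
  list(pairs = pairs, total = sum(w[cbind(pairs, seq_len(n))]))
}
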