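# Independent brute-force oracles used across the suite. These stay
# deliberately naive (enumeration / direct path-walking) and never call
# the implementation paths they check.

# All n! injective column->row pairings, maximized by direct enumeration.
oracle_assignment <- function(w) {
  m <- nrow(w); n <- ncol(w)
  rows <- utils::combn(m, n, simplify = FALSE)
  best <- -Inf
  for (rs in rows) {
    perms <- perms_of(rs)
    for (p in perms) {
      tot <- sum(w[cbind(p, seq_len(n))])
      if (tot > best) best <- tot
    }
  }
  best
}

perms_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# LCS by intersecting full ancestor sets climbed edge-by-edge.
oracle_lcs <- function(tax, c1, c2) {
  climb <- function(cc) {
    seen <- character(0); frontier <- cc
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, function(x) tax$parents[[x]]))), seen)
    }
    seen
  }
  common <- intersect(climb(c1), climb(c2))
  d <- tax$depth[common]
  sort(common[d == max(d)])[1]
}

# Yngve scores by explicit root-path walking per leaf.
oracle_yngve <- function(tree) {
  leaves <- list()
  walk <- function(node, path_idx) {
    if (!is.null(node$token) || is.null(node$children)) {
      leaves[[length(leaves) + 1L]] <<- sum(path_idx)
      return(invisible())
    }
    k <- length(node$children)
    for (j in seq_len(k)) walk(node$children[[j]], c(path_idx, k - j))
  }
  walk(tree, numeric(0))
  unlist(leaves)
}

# Random rooted tree in the parse_ptb nested-list shape with <= max_leaves.
random_tree <- function(max_leaves = 12L) {
  build <- function(n_leaves) {
    if (n_leaves == 1L) return(list(label = "X", token = "w"))
    k <- sample(2:min(3L, n_leaves), 1L)
    sizes <- as.vector(stats::rmultinom(1L, n_leaves - k, rep(1 / k, k))) + 1L
    list(label = "X", children = lapply(sizes, build))
  }
  build(sample(2:max_leaves, 1L))
}

# Random small taxonomy (pure tree) for LCS/similarity property tests.
random_taxonomy <- function(n = 30L) {
  concepts <- c("root", sprintf("n%02d", seq_len(n - 1L)))
  parent <- vapply(seq_len(n - 1L), function(i) concepts[sample(i, 1L)], "")
  counts <- stats::setNames(sample(0:50, n, replace = TRUE), concepts)
  counts["root"] <- counts["root"] + 1L  # nonzero total
  taxonomy(data.frame(child = concepts[-1], parent = parent), counts)
}
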