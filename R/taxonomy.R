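# Rooted is-a concept taxonomy with corpus counts and a word->sense map:
# the substrate for Wu-Palmer, Lin, Resnik, Jiang-Conrath, Leacock-Chodorow
# and path similarities, and for hypernym checks in fluency scoring.

#' Construct a concept taxonomy
#'
#' An is-a taxonomy is a rooted DAG of concepts (multiple inheritance
#' allowed), each with a nonnegative corpus count, plus a word-to-sense map
#' listing each word's concepts in order of decreasing sense frequency.
#'
#' Depth convention: the root has depth 1 and depth is the number of nodes
#' on the longest root-to-concept path, so self-similarity under Wu-Palmer
#' is exactly 1. Information content is `-log2(p)` where `p` is the
#' concept's subtree-summed count over the root's subtree-summed count; a
#' concept whose subtree count is zero gets the maximal IC `-log2(1/total)`.
#'
#' @param edges Two-column data.frame or matrix of `child`, `parent`
#'   concept identifiers.
#' @param counts Named numeric vector of per-concept corpus counts.
#'   Concepts absent from `counts` get count 0.
#' @param senses Named list: word -> character vector of concepts, most
#'   frequent sense first. May be empty.
#' @return Object of class `taxonomy`.
#' @export
taxonomy <- function(edges, counts = NULL, senses = list()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(ncol(edges) >= 2L, nrow(edges) >= 1L)
  names(edges)[1:2] <- c("child", "parent")
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  concepts <- sort(unique(c(edges$child, edges$parent)))
  parents <- split(edges$parent, edges$child)
  children <- split(edges$child, edges$parent)
  roots <- setdiff(concepts, names(parents))
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root; found: ", length(roots))
  root <- roots
  # depth via longest path from root; also detects cycles (no topological order)
  depth <- stats::setNames(rep(NA_integer_, length(concepts)), concepts)
  depth[root] <- 1L
  remaining <- setdiff(concepts, root)
  repeat {
    progressed <- FALSE
    for (cc in remaining) {
      pd <- depth[parents[[cc]]]
      if (!anyNA(pd)) {
        depth[cc] <- max(pd) + 1L
        progressed <- TRUE
      }
    }
    remaining <- names(depth)[is.na(depth)]
    if (length(remaining) == 0L) break
    if (!progressed)
      stop("taxonomy contains a cycle or a concept unreachable from the root")
  }
  cnt <- stats::setNames(rep(0, length(concepts)), concepts)
  if (!is.null(counts)) {
    counts <- counts[names(counts) %in% concepts]
    stopifnot(all(counts >= 0))
    cnt[names(counts)] <- as.numeric(counts)
  }
  # subtree counts: sum of own + descendant counts (each concept once, DAG-safe)
  desc_cache <- new.env(parent = emptyenv())
  descendants <- function(cc) {
    if (!is.null(desc_cache[[cc]])) return(desc_cache[[cc]])
    kids <- children[[cc]]
    out <- cc
    for (k in kids %||% character(0)) out <- c(out, descendants(k))
    out <- unique(out)
    desc_cache[[cc]] <- out
    out
  }
  subtree <- vapply(concepts, function(cc) sum(cnt[descendants(cc)]), 1.0)
  total <- subtree[[root]]
  ic <- if (total > 0) {
    ifelse(subtree > 0, -log2(subtree / total), -log2(1 / total))
  } else stats::setNames(rep(0, length(concepts)), concepts)
  anc_cache <- new.env(parent = emptyenv())
  if (length(senses)) {
    bad <- setdiff(unlist(senses), concepts)
    if (length(bad)) stop("sense concepts not in taxonomy: ", paste(bad, collapse = ", "))
  }
  structure(
    list(concepts = concepts, root = root, parents = parents,
         children = children, counts = cnt, depth = depth,
         subtree = subtree, ic = stats::setNames(as.numeric(ic), concepts),
         senses = senses, .anc_cache = anc_cache),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d concepts, root '%s', max depth %d, %d words in sense map\n",
              length(x$concepts), x$root, max(x$depth), length(x$senses)))
  invisible(x)
}

# Ancestor set including the concept itself (memoized).
tax_ancestors <- function(tax, concept) {
  cached <- tax$.anc_cache[[concept]]
  if (!is.null(cached)) return(cached)
  out <- concept
  frontier <- tax$parents[[concept]] %||% character(0)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unique(unlist(lapply(frontier, function(p) tax$parents[[p]] %||% character(0))))
    frontier <- setdiff(frontier, out)
  }
  out <- unique(out)
  tax$.anc_cache[[concept]] <- out
  out
}

check_concept <- function(tax, concept) {
  if (!concept %in% tax$concepts) stop("unknown concept: ", concept)
}

#' Depth and information content of a concept
#'
#' @param tax A [taxonomy()].
#' @param concept Concept identifier.
#' @return Named numeric `c(depth, ic)`; depth counts nodes on the longest
#'   root path (root = 1), IC is in bits.
#' @export
concept_stats <- function(tax, concept) {
  stopifnot(inherits(tax, "taxonomy"))
  check_concept(tax, concept)
  c(depth = as.numeric(tax$depth[[concept]]), ic = tax$ic[[concept]])
}

#' Least common subsumer of two concepts
#'
#' The common ancestor of maximal depth; depth ties are broken by the
#' lexicographically smallest concept identifier.
#'
#' @inheritParams concept_stats
#' @param c1,c2 Concept identifiers.
#' @return A concept identifier (the root subsumes everything, so a result
#'   always exists).
#' @export
least_common_subsumer <- function(tax, c1, c2) {
  stopifnot(inherits(tax, "taxonomy"))
  check_concept(tax, c1); check_concept(tax, c2)
  common <- intersect(tax_ancestors(tax, c1), tax_ancestors(tax, c2))
  d <- tax$depth[common]
  cands <- sort(common[d == max(d)])
  cands[[1]]
}

#' Taxonomy similarity between two concepts
#'
#' Implements the similarity family used for image-naming scoring, ICU
#' detection and WordNet-style word features:
#' \describe{
#'   \item{wup}{`2*depth(LCS) / (depth(c1)+depth(c2))`, in \[0,1\].}
#'   \item{lin}{`2*IC(LCS) / (IC(c1)+IC(c2))`, in \[0,1\]; defined as 0 when
#'     both ICs are 0 (base-invariant in the IC logarithm).}
#'   \item{resnik}{`IC(LCS)` in bits, >= 0.}
#'   \item{jcn}{`1 / (IC(c1)+IC(c2)-2*IC(LCS) + eps)` with `eps = 1e-10`.}
#'   \item{lch}{`-log(path_len / (2*max_depth))` with node-counting path
#'     length `depth(c1)+depth(c2)-2*depth(LCS)+1`.}
#'   \item{path}{`1 / path_len` with the same path length, in (0,1\].}
#' }
#'
#' @inheritParams least_common_subsumer
#' @param measure One of `"wup"`, `"lin"`, `"resnik"`, `"jcn"`, `"lch"`,
#'   `"path"`.
#' @return List with `measure`, `value`, `lcs`.
#' @export
pairwise_similarity <- function(tax, c1, c2,
                                measure = c("wup", "lin", "resnik", "jcn", "lch", "path")) {
  measure <- match.arg(measure)
  stopifnot(inherits(tax, "taxonomy"))
  check_concept(tax, c1); check_concept(tax, c2)
  lcs <- least_common_subsumer(tax, c1, c2)
  d1 <- tax$depth[[c1]]; d2 <- tax$depth[[c2]]; dl <- tax$depth[[lcs]]
  i1 <- tax$ic[[c1]]; i2 <- tax$ic[[c2]]; il <- tax$ic[[lcs]]
  path_len <- d1 + d2 - 2 * dl + 1  # nodes on the shortest is-a path
  value <- switch(measure,
    wup = 2 * dl / (d1 + d2),
    lin = if ((i1 + i2) == 0) 0 else 2 * il / (i1 + i2),
    resnik = il,
    jcn = 1 / (i1 + i2 - 2 * il + 1e-10),
    lch = -log(path_len / (2 * max(tax$depth))),
    path = 1 / path_len
  )
  list(measure = measure, value = as.numeric(value), lcs = lcs)
}

#' Look up the senses of a word
#'
#' @inheritParams concept_stats
#' @param word Character scalar (matched lowercased).
#' @param mode `"most_frequent"` (first registered sense only) or `"all"`
#'   (registration order preserved).
#' @return Character vector of concepts; empty for out-of-vocabulary words.
#' @export
word_senses <- function(tax, word, mode = c("most_frequent", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tax, "taxonomy"))
  s <- tax$senses[[tolower(word)]] %||% character(0)
  if (mode == "most_frequent" && length(s)) s[1] else s
}

#' Maximum similarity between two words over their senses
#'
#' Every sense pair is compared and the maximum similarity returned, the
#' all-senses convention used for ICU detection.
#'
#' @inheritParams pairwise_similarity
#' @param w1,w2 Words.
#' @param senses `"all"` or `"most_frequent"`.
#' @return Numeric similarity, or `NA` when either word has no sense.
#' @export
word_similarity <- function(tax, w1, w2, measure = "lin",
                            senses = c("all", "most_frequent")) {
  senses <- match.arg(senses)
  s1 <- word_senses(tax, w1, mode = if (senses == "all") "all" else "most_frequent")
  s2 <- word_senses(tax, w2, mode = if (senses == "all") "all" else "most_frequent")
  if (!length(s1) || !length(s2)) return(NA_real_)
  best <- -Inf
  for (a in s1) for (b in s2) {
    v <- pairwise_similarity(tax, a, b, measure)$value
    if (v > best) best <- v
  }
  best
}

#' Read a taxonomy from TSV files
#'
#' @param edges_file TSV with lines `child<TAB>parent`.
#' @param counts_file Optional TSV `concept<TAB>count`.
#' @param senses_file Optional TSV `word<TAB>concept1,concept2,...`.
#' @return A [taxonomy()].
#' @export
read_taxonomy <- function(edges_file, counts_file = NULL, senses_file = NULL) {
  ed <- utils::read.table(edges_file, sep = "\t", header = FALSE,
                          col.names = c("child", "parent"),
                          colClasses = "character", quote = "")
  counts <- NULL
  if (!is.null(counts_file)) {
    ct <- utils::read.table(counts_file, sep = "\t", header = FALSE,
                            colClasses = c("character", "numeric"), quote = "")
    counts <- stats::setNames(ct[[2]], ct[[1]])
  }
  senses <- list()
  if (!is.null(senses_file)) {
    sn <- utils::read.table(senses_file, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
    senses <- stats::setNames(strsplit(sn[[2]], ",", fixed = TRUE), sn[[1]])
  }
  taxonomy(ed, counts, senses)
}

#' Write a taxonomy to TSV files
#'
#' Inverse of [read_taxonomy()]; files are written deterministically
#' (sorted) so identical taxonomies produce byte-identical files.
#'
#' @param tax A [taxonomy()].
#' @param edges_file,counts_file,senses_file Output paths (counts/senses
#'   optional).
#' @return Invisibly, `tax`.
#' @export
write_taxonomy <- function(tax, edges_file, counts_file = NULL, senses_file = NULL) {
  stopifnot(inherits(tax, "taxonomy"))
  kids <- sort(names(tax$parents))
  rows <- unlist(lapply(kids, function(cc)
    paste(cc, sort(tax$parents[[cc]]), sep = "\t")))
  writeLines(rows, edges_file)
  if (!is.null(counts_file))
    writeLines(paste(names(tax$counts), format(tax$counts, trim = TRUE, scientific = FALSE),
                     sep = "\t"), counts_file)
  if (!is.null(senses_file) && length(tax$senses)) {
    w <- sort(names(tax$senses))
    writeLines(paste(w, vapply(tax$senses[w], paste, "", collapse = ","), sep = "\t"),
               senses_file)
  }
  invisible(tax)
}
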