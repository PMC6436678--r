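# Syntactic feature family: POS-profile densities and ratios, syntactic
# complexity (T-unit style) ratios over caller-supplied unit counts, and
# Yngve depth over constituency parse trees. Taggers, parsers and clause
# extraction are upstream tools; their outputs are consumed here.

#' Default Penn-tag to word-class mapping
#'
#' Maps Penn Treebank tags onto the word classes used by the density and
#' ratio features. Editable: pass a modified copy to [count_pos_tags()].
#' Subordinating IN uses is separated from prepositional IN by a
#' subordinator word list; demonstratives and light verbs are identified by
#' surface-form lists.
#'
#' @return Named list of character vectors (`noun`, `verb`,
#'   `inflected_verb`, `adjective`, `adverb`, `preposition`,
#'   `coordinate_conjunction`, `pronoun`, `determiner`, `function_word`
#'   tags; `subordinators`, `demonstratives`, `light_verbs` word lists).
#' @export
default_tag_classes <- function() {
  list(
    noun = c("NN", "NNS", "NNP", "NNPS"),
    verb = c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ", "MD"),
    inflected_verb = c("VBD", "VBG", "VBN", "VBZ"),
    adjective = c("JJ", "JJR", "JJS"),
    adverb = c("RB", "RBR", "RBS", "WRB"),
    preposition = c("IN", "TO"),
    coordinate_conjunction = c("CC"),
    pronoun = c("PRP", "PRP$", "WP", "WP$"),
    determiner = c("DT", "PDT", "WDT"),
    function_word = c("DT", "PDT", "WDT", "IN", "TO", "CC", "PRP", "PRP$",
                      "WP", "WP$", "MD", "EX", "RP"),
    subordinators = c("because", "although", "though", "while", "if",
                      "unless", "since", "whereas", "until", "that",
                      "whether", "after", "before"),
    demonstratives = c("this", "that", "these", "those"),
    light_verbs = c("be", "is", "am", "are", "was", "were", "been", "being",
                    "have", "has", "had", "do", "does", "did", "get", "got",
                    "give", "gave", "go", "went", "make", "made", "take", "took")
  )
}

#' Parse "token/TAG" text
#'
#' @param text Whitespace-delimited `token/TAG` pairs (the last `/` in each
#'   item separates token from tag).
#' @return Data frame with columns `token` (lowercased) and `tag`.
#' @export
read_tagged <- function(text) {
  items <- strsplit(trimws(text), "\\s+")[[1]]
  items <- items[nzchar(items)]
  if (!length(items)) return(data.frame(token = character(0), tag = character(0)))
  pos <- regexpr("/[^/]*$", items)
  if (any(pos < 0)) stop("untagged item in token/TAG input")
  data.frame(
    token = tolower(substr(items, 1L, pos - 1L)),
    tag = substring(items, pos + 1L),
    stringsAsFactors = FALSE
  )
}

#' Count word classes from tagged tokens
#'
#' @param tagged Data frame from [read_tagged()] (columns `token`, `tag`).
#' @param classes Tag-class mapping; see [default_tag_classes()].
#' @return Named numeric vector of per-class counts plus `words` (total),
#'   with subordinate conjunctions split from prepositions by the
#'   subordinator word list.
#' @export
count_pos_tags <- function(tagged, classes = default_tag_classes()) {
  tag <- tagged$tag; tok <- tagged$token
  is_subord <- tag %in% "IN" & tok %in% classes$subordinators
  c(
    nouns = sum(tag %in% classes$noun),
    verbs = sum(tag %in% classes$verb),
    inflected_verbs = sum(tag %in% classes$inflected_verb),
    light_verbs = sum(tag %in% classes$verb & tok %in% classes$light_verbs),
    adjectives = sum(tag %in% classes$adjective),
    adverbs = sum(tag %in% classes$adverb),
    prepositions = sum(tag %in% classes$preposition & !is_subord),
    coordinate_conjunctions = sum(tag %in% classes$coordinate_conjunction),
    subordinate_conjunctions = sum(is_subord),
    pronouns = sum(tag %in% classes$pronoun),
    determiners = sum(tag %in% classes$determiner),
    demonstratives = sum(tag %in% classes$determiner & tok %in% classes$demonstratives),
    function_words = sum(tag %in% classes$function_word),
    words = nrow(tagged)
  )
}

#' POS-profile features: densities and ratios
#'
#' Propositional density
#' `(verbs + adjectives + adverbs + prepositions + conjunctions) / words`,
#' content density `(nouns + verbs + adjectives + adverbs) / words`, the
#' noun-verb, noun, pronoun and subordinate-coordinate ratios, and each raw
#' class count normalized by the word total. Any ratio with a zero
#' denominator is NA.
#'
#' @param pos_counts Named counts from [count_pos_tags()] (requires
#'   `words >= 1`; conjunctions = coordinate + subordinate).
#' @return Named numeric feature vector.
#' @export
pos_features <- function(pos_counts) {
  p <- as.list(pos_counts)
  stopifnot(p$words >= 1)
  conj <- p$coordinate_conjunctions + p$subordinate_conjunctions
  out <- c(
    density_prop = (p$verbs + p$adjectives + p$adverbs + p$prepositions + conj) / p$words,
    density_content = (p$nouns + p$verbs + p$adjectives + p$adverbs) / p$words,
    noun_verb_ratio = safe_ratio(p$nouns, p$verbs),
    noun_ratio = safe_ratio(p$nouns, p$nouns + p$verbs),
    pronoun_ratio = safe_ratio(p$pronouns, p$pronouns + p$nouns),
    subordinate_coordinate_ratio = safe_ratio(p$subordinate_conjunctions,
                                              p$coordinate_conjunctions)
  )
  for (k in setdiff(names(pos_counts), "words"))
    out[paste0(k, "_per_word")] <- pos_counts[[k]] / p$words
  feature_vector(out)
}

#' Syntactic-complexity ratios over clause-unit counts
#'
#' Standard T-unit complexity indices over caller-supplied counts of
#' sentences (S), T-units (T), clauses (C), verb phrases (VP), complex
#' T-units (CT), complex nominals (CN), coordinate phrases (CP) and
#' dependent clauses (DC): mean lengths MLS/MLT/MLC and the ratio set
#' C/S, C/T, CT/T, DC/C, DC/T, CP/C, CP/T, CN/C, CN/T, VP/T, T/S. A zero
#' denominator yields NA (a zero numerator over a positive denominator is
#' a defined 0).
#'
#' @param units Named numeric vector with elements `S`, `T`, `C`, `VP`,
#'   `CT`, `CN`, `CP`, `DC`, `words` (all >= 0).
#' @return Named numeric feature vector.
#' @export
sca_ratios <- function(units) {
  u <- as.list(units)
  needed <- c("S", "T", "C", "VP", "CT", "CN", "CP", "DC", "words")
  stopifnot(all(needed %in% names(u)))
  feature_vector(
    MLS = safe_ratio(u$words, u$S),
    MLT = safe_ratio(u$words, u$T),
    MLC = safe_ratio(u$words, u$C),
    C_S = safe_ratio(u$C, u$S),
    C_T = safe_ratio(u$C, u$T),
    CT_T = safe_ratio(u$CT, u$T),
    DC_C = safe_ratio(u$DC, u$C),
    DC_T = safe_ratio(u$DC, u$T),
    CP_C = safe_ratio(u$CP, u$C),
    CP_T = safe_ratio(u$CP, u$T),
    CN_C = safe_ratio(u$CN, u$C),
    CN_T = safe_ratio(u$CN, u$T),
    VP_T = safe_ratio(u$VP, u$T),
    T_S = safe_ratio(u$T, u$S)
  )
}

#' Parse a bracketed (PTB-style) constituency tree
#'
#' @param s S-expression string, e.g.
#'   `"(S (NP (DT the) (NN cat)) (VP (VBD sat)))"`.
#' @return Nested list tree: internal nodes are
#'   `list(label=, children=list(...))`, leaves are `list(label=tag,
#'   token=word)`.
#' @export
parse_ptb <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  i <- 0L
  nxt <- function() {
    if (i >= length(toks)) stop("malformed tree: unexpected end of input")
    i <<- i + 1L
    toks[i]
  }
  peek <- function() if (i >= length(toks)) "" else toks[i + 1L]
  parse_node <- function() {
    if (nxt() != "(") stop("malformed tree: expected '('")
    label <- nxt()
    if (label %in% c("(", ")")) stop("malformed tree: missing label")
    if (peek() != "(") {  # preterminal: (TAG word)
      word <- nxt()
      if (nxt() != ")") stop("malformed tree: expected ')'")
      return(list(label = label, token = word))
    }
    children <- list()
    while (peek() == "(") children[[length(children) + 1L]] <- parse_node()
    if (nxt() != ")") stop("malformed tree: expected ')'")
    list(label = label, children = children)
  }
  out <- parse_node()
  if (i != length(toks)) stop("malformed tree: trailing input")
  out
}

#' Yngve depth features of a parse tree
#'
#' Yngve depth measures left-branching load: at each internal node children
#' are indexed right-to-left starting at 0, and a leaf's score is the sum
#' of those indices along its root path. Right-branching spines score low,
#' left-branching structures high.
#'
#' @param tree Parse tree from [parse_ptb()] (or the same nested-list
#'   shape).
#' @return Named numeric vector `c(yngve_mean, yngve_max, yngve_total)`
#'   over leaves.
#' @export
yngve_depth <- function(tree) {
  scores <- numeric(0)
  walk <- function(node, acc) {
    if (!is.null(node$token) || is.null(node$children)) {
      scores[[length(scores) + 1L]] <<- acc
      return(invisible())
    }
    k <- length(node$children)
    for (j in seq_len(k)) walk(node$children[[j]], acc + (k - j))
  }
  walk(tree, 0)
  feature_vector(yngve_mean = mean(scores), yngve_max = max(scores),
                 yngve_total = sum(scores))
}

# Mirror a parse tree (reverse all child orders); used by property tests.
mirror_tree <- function(tree) {
  if (!is.null(tree$token) || is.null(tree$children)) return(tree)
  list(label = tree$label, children = rev(lapply(tree$children, mirror_tree)))
}
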