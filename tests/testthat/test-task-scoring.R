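# Shared fixture taxonomy: root -> {animal, artifact}; animal -> {feline,
# canine}; feline -> {cat_c}; counts tuned so word-level lin values
# straddle the 0.75 detection threshold.
scoring_tax <- function() {
  edges <- data.frame(
    child = c("animal", "artifact", "feline", "canine", "cat_c", "chair_c"),
    parent = c("root", "root", "animal", "animal", "feline", "artifact"))
  counts <- c(root = 0, animal = 0, artifact = 4, feline = 2, canine = 2,
              cat_c = 2, chair_c = 4)
  senses <- list(cat = "cat_c", kitten = "cat_c", feline = "feline",
                 dog = "canine", chair = "chair_c", animal = "animal",
                 lion = "feline")
  taxonomy(edges, counts, senses)
}

test_that("image naming scores the best Wu-Palmer match over annotations", {
  tax <- scoring_tax()
  expect_equal(score_image_naming("cat", c("cat", "chair"), tax), 1)
  expect_equal(score_image_naming("zzz", c("cat"), tax), 0)
  expect_warning(sc <- score_image_naming("", c("cat"), tax), "empty")
  expect_equal(sc, 0)
  # response's sense is the annotation's parent at depths 3/4: wup = 2*3/7
  got <- score_image_naming("feline", c("cat"), tax)
  expect_equal(got, 2 * 3 / (3 + 4))
  # chain fixture at depths 2/3 gives the classic 0.8
  chain <- taxonomy(data.frame(child = c("a", "b"), parent = c("root", "a")),
                    senses = list(up = "a", down = "b"))
  expect_equal(score_image_naming("up", c("down"), chain), 0.8)
})

test_that("assignment equals the permutation oracle on 200 random matrices", {
  set.seed(19)
  for (i in 1:200) {
    m <- sample(1:5, 1); n <- sample(1:m, 1)
    w <- matrix(runif(m * n), m, n)
    got <- max_weight_assignment(w)
    expect_equal(got$total, oracle_assignment(w), tolerance = 1e-12)
    expect_equal(length(unique(got$pairs)), n)  # injective
    # Hungarian agrees with exhaustive on the overlap
    expect_equal(max_weight_assignment(w, method = "hungarian")$total,
                 got$total, tolerance = 1e-9)
  }
})

test_that("the greedy-trap instance is solved optimally, and greedy fails it", {
  w <- matrix(c(0.8, 0.1, 0.9, 0.8), 2, 2)  # w[1,]=(0.8,0.9), w[2,]=(0.1,0.8)
  opt <- max_weight_assignment(w)
  expect_equal(opt$total, 1.6)
  expect_equal(opt$pairs, c(1L, 2L))
  greedy <- max_weight_assignment(w, method = "greedy")
  expect_equal(greedy$total, 1.0)
  expect_error(max_weight_assignment(matrix(numeric(0), 0, 0)), "nonempty")
  expect_equal(max_weight_assignment(matrix(0.4, 1, 1))$total, 0.4)
})

test_that("single-word ICU detection honours verbatim, synonym, and threshold rules", {
  tax <- scoring_tax()
  spec <- icu_spec("cat")
  expect_equal(detect_icus(c("the", "cat"), spec, tax)$count, 1)   # verbatim
  expect_equal(detect_icus(c("a", "kitten"), spec, tax)$count, 1)  # lin 1 (same sense)
  expect_equal(detect_icus(c("chair"), spec, tax)$count, 0)
  # manual synonym rescues an OOV word
  spec2 <- icu_spec("cat", manual_synonyms = list(cat = "moggy"))
  expect_equal(detect_icus(c("moggy"), spec2, tax)$count, 1)
  # similarity straddling the threshold: lin(cat, lion) via LCS feline
  s <- word_similarity(tax, "cat", "lion", "lin")
  res75 <- detect_icus(c("lion"), icu_spec("cat", threshold = 0.75), tax)
  expect_equal(res75$count, as.integer(s > 0.75))
  res_low <- detect_icus(c("lion"), icu_spec("cat", threshold = s - 0.01), tax)
  expect_equal(res_low$count, 1)
  res_high <- detect_icus(c("lion"), icu_spec("cat", threshold = min(s + 0.01, 1)), tax)
  expect_equal(res_high$count, 0)
})

test_that("multi-word ICU detection requires the optimal pairing to pass", {
  # two ICU words, both needing > 0.75; engineered similarities reproduce the
  # greedy-trap weight pattern via manual construction of the window
  tax <- scoring_tax()
  spec <- icu_spec("cat dog")
  expect_equal(detect_icus(c("kitten", "dog"), spec, tax)$count, 1)
  expect_equal(detect_icus(c("chair", "dog"), spec, tax)$count, 1)  # window of 1: "dog"
  expect_equal(detect_icus(c("chair", "table"), spec, tax)$count, 0)
  # each ICU counted once despite repeats
  expect_equal(detect_icus(c("cat", "cat", "dog", "dog"), icu_spec(c("cat", "dog")),
                           tax)$count, 2)
})

test_that("ICU detection is monotone in the threshold", {
  set.seed(23)
  tax <- gen_taxonomy(30L, vocabulary_size = 60L, seed = 23L)
  vocab <- names(tax$senses)
  for (i in 1:10) {
    spec_words <- sample(vocab, 4L)
    toks <- sample(vocab, 12L, replace = TRUE)
    sets <- lapply(c(0.5, 0.75, 0.9), function(th)
      detect_icus(toks, icu_spec(spec_words, threshold = th), tax)$detected)
    expect_true(all(sets[[3]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[1]]))
  }
})

test_that("fluency scoring deduplicates and applies dictionary + hypernym checks", {
  tax <- scoring_tax()
  sc <- score_fluency(c("lion", "Lion", "chair"), "animal", "semantic",
                      dictionary = character(0), tax = tax)
  expect_equal(unname(sc), c(1, 1))  # lion via hypernym closure; chair out
  sc2 <- score_fluency(c("weirdword"), "animal", "semantic",
                       dictionary = "weirdword", tax = tax)
  expect_equal(unname(sc2["in_category"]), 1)  # dictionary short-circuits
  sc3 <- score_fluency(c("fish", "fgzq"), "f", "letter",
                       lexicon = c("fish", "dog"))
  expect_equal(unname(sc3), c(1, 0))  # nonword discarded entirely
  sc4 <- score_fluency(c("dog", "fish"), "f", "letter", lexicon = c("fish", "dog"))
  expect_equal(unname(sc4), c(1, 1))
  expect_equal(unname(score_fluency(character(0), "animal", "semantic", tax = tax)),
               c(0, 0))
})

test_that("ROUGE-n recall equals the clipped overlap over reference n-grams", {
  expect_equal(rouge_score(c("the", "cat", "sat"),
                           c("the", "cat", "sat", "on", "the", "mat"), 1), 0.5)
  ref <- c("a", "b", "c", "d")
  expect_equal(rouge_score(ref, ref, 1), 1)
  expect_equal(rouge_score(ref, ref, 2), 1)
  expect_equal(rouge_score(c("x", "y"), ref, 1), 0)
  expect_true(is.na(rouge_score(c("a", "b"), c("a"), 2)))  # reference too short
  # clipping: candidate repeats cannot overcount the reference
  expect_equal(rouge_score(rep("the", 10), c("the", "cat"), 1), 0.5)
})

test_that("BLEU reproduces the hand-evaluated brevity-penalty and precision cases", {
  ref <- c("the", "cat", "sat")
  b1 <- bleu_score(ref, list(ref), max_n = 1)
  expect_equal(b1$score, 1)
  expect_equal(b1$computation$bp, 1)

  b2 <- bleu_score(c("the", "cat"), list(ref), max_n = 1)
  expect_equal(b2$computation$bp, exp(1 - 3 / 2))
  expect_equal(b2$score, exp(-0.5), tolerance = 1e-9)

  # word-count denominator: p2 = 2 matched bigrams / 3 words
  b3 <- bleu_score(ref, list(ref), max_n = 2)
  expect_equal(b3$computation$p_n, c(1, 2 / 3))
  expect_equal(b3$score, sqrt(2 / 3), tolerance = 1e-9)
  # conventional n-gram denominator restores 1
  b4 <- bleu_score(ref, list(ref), max_n = 2, denominator = "ngrams")
  expect_equal(b4$score, 1)

  expect_equal(bleu_score(character(0), list(ref))$score, 0)
  # nearest-length tie resolves to the shorter (harsher) reference
  b5 <- bleu_score(c("a", "b", "c"), list(c("a", "b"), c("a", "b", "c", "d")),
                   max_n = 1)
  expect_equal(b5$computation$r, 2)
  expect_equal(b5$computation$bp, 1)  # r < c branch
})

test_that("choice-task scoring handles keys, polarity and mood pass-through", {
  key <- data.frame(stimulus_id = c("w1", "w2", "g1", "m1"),
                    type = c("choice", "choice", "yesno", "mood"),
                    answer = c("a", "b", "no", ""))
  resp <- data.frame(stimulus_id = c("w1", "w2", "g1", "m1"),
                     response = c("a", "a", "yes", "7"))
  sc <- score_choice_tasks(resp, key)
  expect_equal(sc$value, c(1, 0, 0, 7))
  expect_error(score_choice_tasks(data.frame(stimulus_id = "zz", response = "a"), key),
               "unknown stimuli")
  expect_error(score_choice_tasks(data.frame(stimulus_id = "m1", response = "11"), key),
               "\\[1, 10\\]")
})
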