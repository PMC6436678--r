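test_that("density formulas evaluate as exact rationals of the counts", {
  pc <- c(nouns = 2, verbs = 1, inflected_verbs = 0, light_verbs = 0,
          adjectives = 1, adverbs = 0, prepositions = 1,
          coordinate_conjunctions = 0, subordinate_conjunctions = 0,
          pronouns = 0, determiners = 0, demonstratives = 0,
          function_words = 0, words = 6)
  f <- pos_features(pc)
  expect_equal(unname(f["density_prop"]), 3 / 6)
  expect_equal(unname(f["density_content"]), 4 / 6)
  expect_equal(unname(f["noun_verb_ratio"]), 2)
  expect_equal(unname(f["noun_ratio"]), 2 / 3)

  all_nouns <- pc; all_nouns[] <- 0; all_nouns["nouns"] <- 5; all_nouns["words"] <- 5
  f2 <- pos_features(all_nouns)
  expect_equal(unname(f2["density_content"]), 1)
  expect_equal(unname(f2["density_prop"]), 0)
  expect_true(is.na(f2["noun_verb_ratio"]))  # verbs = 0
  expect_true(is.na(f2["subordinate_coordinate_ratio"]))

  expect_true(all(f[c("density_prop", "density_content")] >= 0 &
                  f[c("density_prop", "density_content")] <= 1))
})

test_that("tagged-text POS counting distinguishes subordinators and light verbs", {
  tg <- read_tagged("the/DT cat/NN sat/VBD because/IN it/PRP was/VBD on/IN the/DT mat/NN")
  pc <- count_pos_tags(tg)
  expect_equal(unname(pc["nouns"]), 2)
  expect_equal(unname(pc["verbs"]), 2)
  expect_equal(unname(pc["subordinate_conjunctions"]), 1)  # "because"
  expect_equal(unname(pc["prepositions"]), 1)              # "on" (not "because")
  expect_equal(unname(pc["light_verbs"]), 1)               # "was"
  expect_equal(unname(pc["words"]), 9)
  expect_error(read_tagged("plain words no tags"), "untagged")
})

test_that("complexity ratios divide correctly and distinguish 0/x from x/0", {
  u <- c(S = 2, T = 2, C = 4, VP = 5, CT = 1, CN = 3, CP = 1, DC = 2, words = 20)
  f <- sca_ratios(u)
  expect_equal(unname(f[c("MLS", "MLC", "C_T")]), c(10, 5, 2))
  expect_equal(unname(f["DC_C"]), 0.5)
  u2 <- u; u2["DC"] <- 0
  expect_equal(unname(sca_ratios(u2)["DC_C"]), 0)      # zero numerator: defined
  u3 <- u; u3["C"] <- 0
  expect_true(is.na(sca_ratios(u3)["CP_C"]))           # zero denominator: missing
  simple <- c(S = 1, T = 1, C = 1, VP = 1, CT = 0, CN = 0, CP = 0, DC = 0, words = 5)
  expect_equal(unname(sca_ratios(simple)[c("C_S", "C_T", "T_S")]), c(1, 1, 1))
})

test_that("Yngve scores match a hand-walked right-branching tree", {
  # (A w1 (B w2 (C w3 w4))): right spine; left child at each level adds 1
  tree <- parse_ptb("(A (X w1) (B (X w2) (C (X w3) (X w4))))")
  f <- yngve_depth(tree)
  # leaves: w1 path idx 1; w2 idx (0,1); w3 (0,0,1); w4 (0,0,0)
  expect_equal(unname(f["yngve_total"]), 1 + 1 + 1 + 0)
  expect_equal(unname(f["yngve_max"]), 1)
  expect_equal(unname(f["yngve_mean"]), 3 / 4)
  single <- parse_ptb("(X w)")
  expect_equal(unname(yngve_depth(single)[c("yngve_mean", "yngve_max")]), c(0, 0))
})

test_that("mirroring a right-branching tree does not decrease mean Yngve depth", {
  tree <- parse_ptb("(A (X w1) (B (X w2) (C (X w3) (X w4))))")
  f <- yngve_depth(tree)
  fm <- yngve_depth(langscore:::mirror_tree(tree))
  expect_gte(unname(fm["yngve_mean"]), unname(f["yngve_mean"]))
})

test_that("Yngve agrees with the brute-force path-walk oracle on random trees", {
  set.seed(13)
  for (i in 1:100) {
    tr <- random_tree(12L)
    scores <- oracle_yngve(tr)
    f <- yngve_depth(tr)
    expect_equal(unname(f["yngve_mean"]), mean(scores))
    expect_equal(unname(f["yngve_max"]), max(scores))
    expect_equal(unname(f["yngve_total"]), sum(scores))
  }
})

test_that("parse_ptb rejects malformed bracketings", {
  expect_error(parse_ptb("(A (B w)"), "malformed")
  expect_error(parse_ptb("(A (B w)) extra"), "malformed")
})

test_that("cosine distance features match hand-computed binary-vector geometry", {
  f <- cosine_features(list(c("a", "b"), c("a", "c")))
  expect_equal(unname(f["cos_dist_mean"]), 0.5)   # cos((1,1,0),(1,0,1)) = 1/2
  f2 <- cosine_features(list(c("a", "b"), c("a", "b")))
  expect_equal(unname(f2["cos_dist_min"]), 0)
  f3 <- cosine_features(list(c("a"), c("b")))
  expect_equal(unname(f3["cos_dist_mean"]), 1)    # orthogonal
  expect_true(all(is.na(cosine_features(list(c("a"))))))
  # ordering invariant: 0 <= min <= mean <= 1
  set.seed(21)
  for (i in 1:20) {
    utts <- replicate(sample(2:5, 1),
                      sample(letters[1:6], sample(1:4, 1)), simplify = FALSE)
    g <- cosine_features(utts)
    expect_gte(g[["cos_dist_min"]], 0 - 1e-12)
    expect_lte(g[["cos_dist_min"]], g[["cos_dist_mean"]] + 1e-12)
    expect_lte(g[["cos_dist_mean"]], 1 + 1e-12)
  }
})

test_that("cutoff proportion counts pairs at distance <= threshold", {
  utts <- list(c("a", "b"), c("a", "b"), c("z"))
  f <- cosine_features(utts, threshold = 0.5)
  # pairs: (1,2) d=0; (1,3) d=1; (2,3) d=1 -> 1 of 3 within cutoff
  expect_equal(unname(f["cos_cutoff_prop"]), 1 / 3)
})

test_that("taxonomy word features report specificity, ambiguity and coverage", {
  tax <- taxonomy(data.frame(child = c("a", "b"), parent = c("root", "root")),
                  senses = list(mono = "a", poly = c("a", "b")))
  f <- wordnet_word_features(c("mono", "poly"), tax)
  expect_equal(unname(f["specificity_mean"]), 2)  # both root children
  expect_equal(unname(f["ambiguity_mean"]), 1.5)
  expect_equal(unname(f["taxonomy_coverage"]), 1)
  f2 <- wordnet_word_features(c("zzz", "qqq"), tax)
  expect_true(is.na(f2["specificity_mean"]))
  expect_equal(unname(f2["taxonomy_coverage"]), 0)
})
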