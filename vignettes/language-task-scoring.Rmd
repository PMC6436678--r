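---
title: "Scoring cognitive language tasks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cognitive language tasks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langscore)
```

`langscore` implements the computational layer of a remote
language-assessment battery: automated scorers for six task types,
four families of linguistic features, per-stimulus score normalization,
and a canonical-correlation procedure for transferring a normatively
trained representation to an external dataset. This vignette explains
each method, its assumptions, the parameters that matter, and the design
choices made where the published conventions are genuinely open.

## Text primitives

Tokenization is deliberately minimal and deterministic: lowercase, split
on whitespace, strip leading/trailing punctuation, keep word-internal
apostrophes and hyphens. Typed text is split into sentences at `.`, `!`,
`?` followed by whitespace; for spoken transcripts each utterance counts
as one sentence, since utterance segmentation happens upstream of this
package. Because no standard tokenizer is canonical for transcript-style
input, token counts from other toolchains may differ slightly; every
count-derived feature here is defined relative to this tokenizer.

Syllables are counted as maximal vowel-letter groups (a, e, i, o, u, y)
with a trailing silent-e adjustment (not applied to `-le` endings) and a
floor of one. This is the standard heuristic family used for
Flesch-style readability scoring; it is not a phonological syllabifier,
and readability values should be read as the heuristic's output, not
ground truth syllabification.

Empty or whitespace-only samples raise a classed condition
(`langscore_empty_sample`) rather than propagating zero divisions;
feature extractors skip such samples.

## Taxonomy similarity

All semantic scoring rests on a rooted is-a concept DAG with per-concept
corpus counts and a word-to-sense map (most frequent sense first). Two
conventions pin down the numbers:

- **Depth**: the root has depth 1 and depth counts nodes on the longest
  root path. This makes Wu–Palmer self-similarity exactly 1, which the
  image-naming scorer relies on.
- **Information content**: `IC(c) = -log2(count_subtree(c) / count_subtree(root))`,
  where subtree counts sum the corpus counts of a concept and all its
  descendants (each counted once in a DAG). A concept with zero subtree
  mass gets the maximal IC `-log2(1/total)`. Lin similarity is a ratio
  of logs of the same quantities, so the log base cancels; base 2 is
  used for reporting ICs in bits.

Supported measures: Wu–Palmer, Lin, Resnik (`IC(LCS)`), Jiang–Conrath
(`1/(IC(c1)+IC(c2)-2·IC(LCS)+1e-10)`; the epsilon only guards the
identical-concept pole), Leacock–Chodorow and inverse path length. The
path length is node-counting (`depth(c1)+depth(c2)-2·depth(LCS)+1`), so
`path(c,c) = 1` and Leacock–Chodorow is finite at identity. Ties among
deepest common ancestors break to the lexicographically smallest
identifier, making results order-independent.

The corpus behind the ICs is an interchangeable input. Absolute Lin
values therefore depend on the counts file supplied; only the procedure
(and everything tested here) is corpus-independent.

## Task scorers

**Image naming.** Response and annotations map to their most-frequent
sense; the score is the maximum Wu–Palmer similarity over annotations.
Out-of-vocabulary responses score 0 — a conservative choice that avoids
crediting typos, at the cost of occasionally zeroing a legitimate rare
word.

**Picture description (ICU detection).** A single-word ICU is detected
if some transcript word matches it verbatim, is a manually listed
synonym, or exceeds the similarity threshold under Lin similarity
maximized over *all* sense pairs. The threshold defaults to 0.75 and the
comparison is strict (`>`). For an `m`-word ICU, every contiguous window
of `n ≤ m` transcript words is compared by solving a maximum-weight
bipartite assignment over pairwise word similarities; the ICU is
detected only if every matched pair exceeds the threshold. Surplus ICU
words (when `n < m`) are ignored — the alternative of requiring the
assignment *total* to pass was rejected because a single weak pair can
then hide behind a strong partner, which is exactly the failure the
per-pair rule prevents. Each ICU counts at most once, so the information
score is the number of distinct ICUs mentioned. Detection is monotone in
the threshold by construction.

The assignment solver enumerates injective pairings exhaustively up to 8
window words and switches to an O(n³) shortest-augmenting-path method
above that; both are exact and are cross-checked against each other and
against a permutation oracle in the tests. A greedy matcher is included
for comparison only: on weights like `[[0.8, 0.9], [0.1, 0.8]]` greedy
takes the 0.9 pair and strands its neighbour at 0.1, missing a detection
the optimal pairing finds.

**Fluency.** Responses are deduplicated case-insensitively. Semantic
variant: a word is in-category if it is in the stimulus dictionary, or
if the category concept is an ancestor of any of its senses. Letter
variant: nonwords (absent from the validity lexicon, by default the
sense-map vocabulary) are discarded entirely; valid words split by
initial letter. All remaining unique words count as out-of-category.

**Story recall.** ROUGE-n recall: clipped matched n-gram count over the
reference n-gram count, for unigrams and bigrams, with the source story
as the reference.

**Vocabulary.** BLEU with brevity penalty `BP = 1` if `r < c`, else
`exp(1 - r/c)`, where `r` is the reference length nearest to the
candidate length `c` (ties resolve to the *shorter* reference — the
harsher penalty, so scores never benefit from ambiguity). The per-order
precision divides the clipped matched n-gram count by the **candidate
word count** at every order. This word-count denominator is the package
default; the conventional per-order n-gram-count denominator is
available via `denominator = "ngrams"`. The two coincide at `n = 1` and
differ by `(c - n + 1)/c` otherwise; results should state which
convention was used.

**Choice tasks.** Pronoun-resolution items score 1/0 against the key;
yes/no self-report items map to 0/1 through a per-item polarity; mood
ratings pass through on [1, 10].

## Feature families

**Lexical.** Type–token ratio `U/N`; moving-average TTR over sliding
windows of 10–50 tokens (step 1; samples shorter than the window yield a
missing value rather than a shrunken window, so MATTR values are always
comparable across samples); Brunet index `N^(U^-0.165)` (lower
vocabulary richness gives larger values); Honoré statistic
`100·ln(N)/(1 - N1/U)` with natural log. When every type is a hapax
(`N1 = U`) the Honoré statistic is undefined and reported missing, never
infinite. Flesch reading ease and Flesch–Kincaid grade level use the
standard constants (206.835, −1.015, −84.6; 0.39, 11.8, −15.59); a
`fk_printed_constant` flag flips the final FK constant to +15.59 to
reproduce a sign variant that circulates in some secondary write-ups.
Norm features (frequency, age-of-acquisition, imageability, familiarity,
arousal, dominance, valence) report mean, SD and coverage per dimension
over in-lexicon tokens; polarity features numerically code categorical
labels (default −2/−1/+1/+2 for the four-level scheme) and add
per-category proportions. All "undefined" cases are explicit `NA`s — no
NaN or Inf ever leaks into a feature vector.

**Syntactic.** Propositional density
`(verbs+adjectives+adverbs+prepositions+conjunctions)/words` and content
density `(nouns+verbs+adjectives+adverbs)/words`; noun–verb, noun,
pronoun and subordinate–coordinate ratios; every class count also
normalized by words. POS tags are consumed from pre-tagged `token/TAG`
input — tagging itself is out of scope — through an editable
Penn-tag-to-class table; subordinating uses of `IN` are separated from
prepositions by a subordinator word list, and demonstratives and light
verbs by surface-form lists. T-unit complexity ratios (MLS, MLT, MLC,
C/S, C/T, CT/T, DC/C, DC/T, CP/C, CP/T, CN/C, CN/T, VP/T, T/S) are
computed from caller-supplied unit counts; clause extraction is an
upstream tool's job. Zero denominators yield missing; a zero *numerator*
over a positive denominator is a defined 0 — conflating the two would
bias complexity ratios downward on short samples. Yngve depth indexes
children right-to-left from 0 and sums indices along each leaf's root
path; mean, max and total over leaves quantify left-branching load.

**Semantic.** Utterances embed as binary bag-of-types vectors over the
transcript vocabulary; mean and minimum pairwise cosine distance plus
the fraction of pairs at distance ≤ 0.5 (the cutoff is configurable; 0.5
is the natural midpoint of the distance range and marks pairs sharing a
substantial fraction of vocabulary). Word specificity (depth of the
most-frequent sense) and ambiguity (sense count) average over
in-taxonomy tokens.

**Timing.** From word alignments (`word onset offset`, seconds):
inter-word gaps above 150 ms are pauses; short pauses lie strictly
inside (150 ms, 400 ms); the 400 ms boundary is assigned to long pauses
so the two bands partition the pauses. Gaps are rounded to microseconds
before banding so millisecond-precision alignment files hit the band
edges exactly. Features: total duration, active-speech ratio, mean
pause / short-pause / long-pause lengths (missing when a band is empty),
pause-to-segment count ratio, and a separately named
pause-to-speech *duration* ratio — the count/duration ambiguity is
resolved by providing both under distinct names. Leading and trailing
silence are not pauses: pauses are inter-word by definition here, since
file-edge silence mostly measures recording habits.

## Normalization and analysis

**Per-stimulus CDF equalization.** Within each stimulus,
`x -> (# scores ≤ x)/n`. Ties share a value; output lies in (0, 1]. The
transform is invariant to strictly increasing rescalings of raw scores
and makes every stimulus's scores discretely uniform, which removes
stimulus difficulty: per-stimulus means become identical by
construction, so the between-stimulus variance component vanishes.
Singleton groups map to 1 with a warning. For binary tasks (where a CDF
is uninformative), the simplicity-weighted average
`Σ w_j x_j / Σ w_j` is used instead, with `w_j` the observed rate of
correct responses to item `j`; normalizing by `Σ w` (not item count)
keeps the score in [0, 1] and makes missing an easy item strictly worse
than missing a hard one. Multi-session subjects average normalized
scores over sessions.

**KL divergence** between per-stimulus score samples uses
integer-centered unit bins spanning both samples, additive smoothing
`1e-6` (renormalized) for finiteness on disjoint supports, and is
reported in nats; a matrix helper linearly rescales off-diagonals to
[0, 1] for display.

**Cross-task correlations.** Pearson rho with two-sided p-values over
pairwise-complete subjects; entries are masked when same-task or when
`p > 0.05` with *no* multiple-testing correction — the display-level
convention for these correlation maps. An optional Benjamini–Hochberg
flag exists for users who want the corrected view. Constant columns
yield missing, masked correlations.

**PCA** of within-task metrics is standard standardized-variable
`prcomp`; asking for more components than the data rank is an error
rather than a silent truncation.

**CCA.** Both views are standardized (zero-variance columns get SD 1 so
projection never divides by zero); the solver whitens with
`(S11 + ridge·I)^(-1/2)` and takes the SVD of the whitened
cross-covariance. Ridge defaults to `1e-3` — enough to handle the
near-collinearity typical of feature families — and `ridge = 0` rejects
rank-deficient views with guidance instead of silently pseudo-inverting.
The embedding count defaults to 20, capped at the smaller view
dimension. Canonical correlations are non-increasing and clamped to
[0, 1]. With `ridge -> 0` the correlations are invariant to invertible
linear transforms of either view (verified to 1e-6 in the tests); with
positive ridge this invariance is deliberately traded for stability.
`cca_augment` projects external samples that share view 1's feature
space through the stored standardization and projection, then
concatenates caller-selected original features, giving a
`k + m`-column design matrix for downstream classifiers. The downstream
evaluation harness (feature selection, kernel classifiers, nested CV)
is intentionally out of library scope: it is experiment code, not a
reusable method.

## Synthetic fixtures: what they do and do not show

Every input format has a seeded generator: random rooted taxonomies with
Zipf-distributed concept counts and controlled polysemy; norm lexicons
with realistic ranges (age-of-acquisition 2–17 years, valence 1–9,
etc.); transcripts whose measurable properties are *monotone in a
quality parameter* (fraction of ICUs mentioned, n-gram overlap with a
source story, in-category count), with planted inter-word gaps for the
timing features; and score cohorts following
`score = loading_task·ability + difficulty + noise` with
`ability ~ N(0, 1)`, per-stimulus `difficulty ~ N(0, 1)` and noise SD
0.5 (binary tasks go through a logistic link). One master seed fans out
to independent per-generator streams, so generation is bit-reproducible
and insensitive to call order.

These fixtures validate *formulas, contracts and invariants*: that the
scorers compute what they claim, that normalization removes planted
difficulty, that CCA recovers a planted shared latent. They do not
emulate disfluent natural speech, recognition errors, tagger noise, or
real lexical statistics, so passing tests demonstrate correctness of the
computations — not clinical validity of the scores on human data.

Problem sizes used in the test suite were chosen to make the statistical
checks stable at small cost: 500 subjects × 10 stimuli × 20 seeds for
the equalization checks, n = 1000 with noise SD 0.1 for the CCA
recovery simulation, 200 random matrices up to 5×5 against the
assignment oracle, 100 random trees for the Yngve oracle, and a
12-subject bundle for the end-to-end pipeline.

## Known limitations

- The tokenizer and syllable heuristic are deterministic simplifications;
  counts from other NLP stacks will differ in edge cases.
- Absolute Lin/Resnik/Jiang–Conrath values depend on the supplied count
  corpus; only Wu–Palmer and path measures are corpus-free.
- ICU detection has no grammatical sensitivity: negations ("no cookie
  jar") still count the ICU, and word order within a window is ignored.
- The BLEU word-count denominator makes multi-order scores
  systematically lower than standard BLEU; comparisons across toolkits
  must align the flag.
- CDF equalization guarantees marginal uniformity only per stimulus
  group; with few observations the output is coarsely discrete.
- POS, parse-tree and clause-unit features are only as good as the
  upstream tagger/parser whose output is consumed.
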