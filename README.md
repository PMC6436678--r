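# langscore

Automated scoring and linguistic feature extraction for cognitive
language-assessment tasks.

Remote language-assessment batteries collect typed responses and speech
transcripts for tasks such as naming pictured objects, describing a complex
scene, listing category members under time pressure, retelling a short
story, defining words, and answering pronoun-resolution or mood questions.
`langscore` provides the computational layer for such a battery:

- **Task scorers.** Image naming is scored by Wu–Palmer taxonomy similarity
  between the response and the image annotations,
  `sim_wup = 2·depth(LCS(c1,c2)) / (depth(c1)+depth(c2))`. Picture
  description is scored by counting information content units (ICUs)
  detected via Lin similarity `sim_lin = 2·IC(LCS) / (IC(c1)+IC(c2))` with
  acceptance threshold 0.75; multi-word ICUs are matched to transcript
  windows by maximum-weight bipartite assignment, because greedy word
  pairing is provably suboptimal. Fluency responses are split into in- and
  out-of-category counts using stimulus dictionaries plus a hypernym check.
  Story recall uses ROUGE-1/ROUGE-2 recall against the source story;
  vocabulary definitions use BLEU
  (`BP·(p1···pn)^(1/n)` with `BP = exp(1 − r/c)` for `r ≥ c`) against
  reference definitions; choice tasks score 0/1 against an answer key.
- **Feature families.** Lexical (type–token ratio, moving-average TTR,
  Brunet index `N^(U^-0.165)`, Honoré statistic `100·ln N / (1 − N1/U)`,
  Flesch and Flesch–Kincaid readability, psycholinguistic norms,
  polarity), syntactic (POS densities and ratios, T-unit complexity
  ratios, Yngve depth), semantic (utterance cosine distances, taxonomy
  specificity/ambiguity) and timing (pause and duration statistics from
  word alignments, with the 150 ms / 400 ms short/long pause bands).
- **Normalization and analysis.** Per-stimulus empirical-CDF score
  equalization (removes stimulus difficulty), simplicity-weighted
  averaging for binary tasks, KL divergence between per-stimulus score
  distributions, significance-masked cross-task Pearson correlations,
  within-task PCA, and regularized canonical correlation analysis (CCA)
  for projecting an external dataset into a shared space learned from two
  feature views.
- **Synthetic fixtures.** Seeded generators for taxonomies, lexicons,
  transcripts and score cohorts with known ground truth, so the entire
  pipeline runs and is tested offline.

## Worked example

```r
library(langscore)

# a tiny is-a taxonomy: root -> a -> b
tax <- taxonomy(data.frame(child = c("a", "b"), parent = c("root", "a")),
                counts = c(root = 12, a = 3, b = 1),
                senses = list(up = "a", down = "b"))
pairwise_similarity(tax, "a", "b", "wup")$value
#> [1] 0.8
score_image_naming("up", c("down"), tax)
#> [1] 0.8

bleu_score(c("the", "cat"), list(c("the", "cat", "sat")), max_n = 1)$score
#> [1] 0.6065307

f <- timing_features(data.frame(onset_s = c(0, 0.7, 1.5),
                                offset_s = c(0.5, 1.0, 2.0)), 2.0)
f[c("pause_mean", "active_ratio")]
#> pause_mean active_ratio
#>       0.35         0.65
```

The Wu–Palmer value 0.8 is `2·2/(2+3)`: the least common subsumer `a`
sits at depth 2 and the two concepts at depths 2 and 3. The BLEU value is
the pure brevity penalty `exp(1 − 3/2)` — the two-word candidate matches
the reference perfectly but is penalized for being short. The pause
features are read off the two inter-word gaps (0.2 s and 0.5 s): mean
pause 0.35 s and 65% active speech.

A full pipeline run over a generated fixture bundle:

```sh
Rscript inst/cli/langscore simulate  --out bundle --seed 4
Rscript inst/cli/langscore score     --sessions bundle --out scores.csv
Rscript inst/cli/langscore extract   --sessions bundle --out features.csv
Rscript inst/cli/langscore normalize --scores scores.csv --out normalized.csv
Rscript inst/cli/langscore analyze   --scores normalized.csv --out analysis --cca-k 2
```

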