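---
title: "Methods: tract-level food-desert signals from geotagged text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tract-level food-desert signals from geotagged text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the approach

A *food desert* is a census tract that is simultaneously **low-income**
and **low-access** under the USDA Food Access Research Atlas definitions.
Official identification is infrequent; `foodsignal` implements an
infodemiology alternative: treat geotagged short-text posts as passive
observations of food ingestion language, aggregate them to census
tracts, and ask (a) which tract-level language features are associated
with food-desert status after adjusting for demographics, and (b) how
much those features improve a classifier that predicts food-desert
status from socioeconomic covariates alone.

The pipeline has seven stages — ingest filters, keyword matching,
sentiment scoring, tract mapping, feature aggregation with USDA
labeling, an adjusted linear screen, and a classification benchmark —
plus a synthetic-data generator that emulates every input so the chain
can be exercised end to end without a proprietary corpus.

## Ingest filters

Three filters, in order:

* **Geolocation**: both coordinates present and in range (lat within
  ±90, lon within ±180). Range validation happens here, not at parse
  time, so raw record counts stay reportable.
* **Promotional exclusion**: a post is dropped when its lowercased text
  contains a blocklist entry as a whole whitespace-delimited token
  (default `#jobs`, `#hiring`, `#ad`, `#job`). Token matching, not
  substring matching: `#AdVice` survives `#ad`, and "job" in running
  prose is untouched. The blocklist is user-configurable because no
  finite list of promotional tags is canonical.
* **Food relevance**: at least one keyword match (below). Reposts and
  duplicate texts under distinct ids are retained.

Each filter is idempotent, the geolocation and promotional filters
commute (they inspect disjoint fields), and corpus size is monotonically
non-increasing along the chain — all properties under test.

## Keyword matching

Matching is greedy and longest-first. The lexicon indexes keywords by
word count; for k = max..1, every occurrence of a k-word keyword over
contiguous, not-yet-consumed tokens is recorded and its tokens marked
consumed. This is what prevents a "Burger King" mention from also being
counted as "burger": the two-word phrase is found first and removes its
tokens from consideration.

Decisions the published procedure leaves open, resolved here:

* **Tokenization**: lowercase; URLs and @-mentions stripped; `#`
  removed from hashtags; split on non-alphanumeric boundaries. One
  canonical token stream feeds both matching and sentiment so the two
  stages can never disagree about what a "word" is.
* **Plural folding**: a text token matches a one-word keyword after
  removing one trailing "s" ("burgers" → "burger"); an exact lexicon
  hit takes precedence, and `plural_fold = FALSE` restores exact-only
  matching. Multi-word phrases match exactly.
* **Determinism**: within a word-count level, occurrences are consumed
  left to right; a token contributes to at most one match. Repeated
  occurrences of the same keyword are all counted — mention *counts*,
  not indicators, feed the tract features.
* Degenerate inputs: empty text yields an empty match list; a zero-match
  post inside a supposedly food-filtered corpus is an
  internal-consistency error, not a silent skip.

The implementation is checked against an independently written
exhaustive oracle (candidate enumeration + greedy longest-first
selection) on 10,000 random text/lexicon cases.

## Per-post scoring and sentiment

A post's nutrient profile is the **available-case mean** over matched
items, per nutrient: fast-food brand names carry no nutrient row and
must not zero out the average, so each nutrient averages over the items
that have it and is missing only when no matched item does. Calorie
means are additionally computed within the healthy and unhealthy
categories.

Sentiment is a plain polarity-lexicon sum: +1 per positive word, −1 per
negative word, 0 otherwise, summed over all tokens (repeats count).
The sign gives the label; a score of exactly 0 is neutral. No negation
handling is attempted — the method is deliberately the simple lexicon
sum. Six flags are derived per post: for each food category mentioned at
least once, the flag matching the label's polarity (neutral posts set
none). Sentiment words inside matched food phrases are still scored;
the score uses the full original token stream.

## Tract mapping

The default assignment mode follows the published method literally:
point to **bounding box**, edges inclusive (half-open conventions would
silently drop grid-aligned synthetic points). Real adjacent tracts have
overlapping boxes, which the published description does not
disambiguate, so the assignment is made total and deterministic: the
smallest-area box wins, remaining ties break lexicographically by tract
id. `mode = "polygon"` offers the geometrically exact alternative
(bbox prefilter, then point-in-polygon via `mgcv::in.out`, verified
against a hand-written ray-casting oracle).

## Tract features and USDA labeling

Per tract with at least one mapped food-related post:

* six sentiment percentages = 100 × flagged posts / all food-related
  posts in the tract (neutral posts stay in the denominator, never in a
  numerator);
* three mean mention counts (means of per-post category counts);
* 17 nutrient means plus healthy/unhealthy calorie means, each the
  available-case mean of per-post means.

Tracts with zero food-related posts are excluded from the analysis
table. SES covariates (12 fields) are merged by inner join; duplicates
on either side are errors.

Labeling is the USDA conjunction, all boundaries inclusive:
**low-income** = poverty ≥ 20%, or median family income ≤ 80% of the
state median, or ≤ 80% of the metro median (applied only when a metro
income is supplied — the criterion is conditional on metro membership);
**low-access** = ≥ 500 people or ≥ 33% of residents far from a
supermarket, with the access inputs consumed pre-measured at the
appropriate 1-mile/10-mile distance as the Atlas supplies them.
Labeling is monotone in poverty and access, under test.

## The association screen

For each of the 28 features y:

y = β₀ + β_FD·x_FD + β₁x₁ + … + β₁₂x₁₂ + ε

fit by OLS (QR decomposition), with the food-desert indicator as
treatment and the 12 SES covariates untransformed as controls (min-max
scaling belongs to the classification stage only). Two-sided t-test
p-values on β_FD with n − 14 degrees of freedom; **no multiple-testing
correction**, matching the screening character of the procedure — raw
p-values are reported. Missing feature values (tracts whose posts never
carried a nutrient) are dropped listwise per feature, with deletion
counts reported. Conventions: an all-constant outcome returns β = 0,
R² = 0, p = 1; a rank-deficient design is an error naming the collinear
columns. The fit is verified against a direct normal-equations solve to
1e-8 relative tolerance, and 95% CI coverage of an implanted effect is
checked over 200 replicates.

## The classification benchmark

Five feature sets: (1) the 12 SES covariates; (2) + the 19 nutrient
features; (3) + the 6 sentiment percentages; (4) + both; (5) + whatever
the screen found significant. Four methods per set:

* **adaptive boosting** — exponentially reweighted decision stumps
  (`rpart` stumps; the classic discrete-boosting update, score =
  logistic transform of the weighted vote);
* **gradient boosting** — shallow trees on logistic loss (`xgboost`,
  single-threaded for determinism);
* **logistic regression** — maximum-likelihood linear logit (`glm`);
* **ensemble** — stacking: out-of-fold base scores on the training rows
  train a logistic meta-learner; at prediction time full-training base
  models feed it.

Protocol decisions:

* **Stratified** 70:30 split and stratified 5-fold CV — with ~7.5%
  positives, unstratified folds risk single-class folds; a degenerate
  fold is refolded with a shifted seed and logged.
* CV selects hyperparameters from small fixed grids (stump rounds
  {40, 80}; tree depth {2, 3} × rounds {60, 120} at learning rate 0.1);
  the reported AUC is always on the untouched 30% test split.
* Min-max normalization is fit on **training rows only** (a leakage
  test asserts pooled scaling would change the result); test values are
  not clipped. A constant training column maps to zero.
* Missing nutrient features are imputed with the training-set median
  before scaling; no indicator columns.
* No class re-weighting or resampling — class imbalance is addressed
  only through the choice of AUC as the metric.
* AUC is computed in the Mann-Whitney rank form with half credit for
  ties, verified exactly against O(n²) pair counting.

Whether normalization preceded or followed the original 70:30 split is
not stated in the published procedure; the train-only choice here is
this package's own (leakage-safe) decision.

## The synthetic generator

The generator emulates all five inputs with one seed fixing everything:

* **Tracts** are disjoint unit squares on a grid, so bbox and polygon
  assignment agree and geometry cannot confound statistical tests
  (overlap handling is exercised by dedicated unit fixtures instead).
* **SES** fields are drawn near published tract-level means/SDs (e.g.
  median family income ~ N(82371, 42680²) truncated, poverty ~
  N(16.2, 12.1²)). Race shares are drawn independently (they need not
  sum to 100 — adequate for covariate adjustment, not a joint
  demographic model). Exactly `round(n_tracts × food_desert_fraction)`
  tracts (default fraction 0.0752) receive poverty in [22, 45] and a
  low-access share in [35, 70], satisfying the USDA conjunction; every
  other tract fails both access criteria while its income and poverty
  vary freely. The construction is verified by round-tripping through
  the labeler.
* **Tweets per tract** ~ NB(size 0.7, mean 5): conditional on at least
  one post, median 4 and IQR 7 — the closest a two-parameter negative
  binomial gets to the observed per-tract volume (median 4, IQR 8).
* **Texts** are templated filler English plus 1–3 food keywords and at
  most one polarity word, with random unit order and occasional mixed
  case; no real user content is imitated. Promotional, non-geolocated,
  and keyword-free posts are injected (3% each) to exercise the
  filters.
* **Effects are implanted at the sampling-probability level**, never by
  editing aggregated features, so a recovered effect proves every stage
  transmitted it: in desert tracts, an extra unhealthy mention with
  probability 0.35; the positive-word probability boosted by +0.30 for
  healthy-mentioning and +0.40 for fast-food-mentioning posts (base
  positive/negative probabilities 0.35/0.25); and keyword choice tilted
  by exp(+1.0·z(cholesterol) − 1.0·z(potassium)) within category —
  one standard deviation of exponential tilt per unit log-weight.

### Calibration of the effect block

The published associations fix only the *signs* of the five implanted
effects (+ healthy-positive share, + fast-food-positive share,
+ unhealthy mentions, + cholesterol, − potassium). The magnitudes are
this package's choice, set by a power requirement the generator imposes
on itself: at 1000 tracts and 7.52% prevalence, the screen should
recover all five with correct signs in at least 90% of replicates —
otherwise the default conditions could not distinguish a working
pipeline from a broken one. A first analytic calibration targeted
tract-level standardized effects of 0.5–1.0 SD but under-counted the
variance contributed by one- and two-post tracts (E[1/n | n>0] ≈ 0.4
under the NB volume model, not the 0.3 first assumed), leaving the
fast-food sentiment effect at ~89% per-feature recovery; the two
sentiment boosts were raised (healthy +0.25 → +0.30; fast food
+0.30 → +0.40) to meet the requirement, and the three non-sentiment
deltas were left at their initial values. Measured recovery at the defaults: per-feature ≥ 0.97,
joint 0.97. The keyword tilt deliberately drags correlated nutrients
(fat, saturated fat) along with cholesterol — real food co-occurrence
does the same — so screens on default data flag a handful of correlated
nutrient features beyond the five targets.

With all deltas zero the generator is an exact null: desert and
non-desert tracts share one text-generating distribution, and the
screen's per-feature rejection rate at α = 0.05 is verified to sit in
[0.03, 0.07] over 500 replicates.

### What the generator does not emulate

Real corpus features deliberately out of scope: language beyond
templated filler (no misspellings, emoji, named entities, or negation),
the streaming API's 1% sampling, monthly volume structure, user-level
clustering of posting behavior, spatial autocorrelation between
neighboring tracts, and real city geography. Passing tests therefore
demonstrate that the *pipeline* is correct and transmits implanted
signal — not that real posts carry signal of any particular strength.

## Problem sizes and runtime conventions

The shipped checks use sizes chosen to make their statistical claims
sharp at desk scale: 10,000 matcher oracle cases; 1,000 AUC oracle
instances; 100 random OLS designs plus 200 coverage replicates at
n = 500; 500 null-calibration replicates at 120 tracts and 100 recovery
replicates at 1000 tracts; benchmark direction checks at 800–1200
tracts; and a bit-reproducibility check of the full chain at 500
tracts. The acceptance script's end-to-end run uses 500 tracts.

## Known limitations

* Bounding-box assignment (the published default) misassigns points in
  concave or overlapping real tract geometries; polygon mode is exact
  but slower.
* The sentiment model is a bare polarity sum: negation ("not good"),
  sarcasm, and intensity are all invisible.
* The screen fits 28 unadjusted-for-multiplicity models by design;
  its significant set is a screening device for model 5, not a
  confirmatory analysis.
* Tract features built from very few posts are noisy; the pipeline
  reports `n_tweets` per tract but does not down-weight small tracts.
* `glm` logistic fits can warn on separable synthetic data; warnings
  are suppressed and scores remain valid for ranking (AUC) purposes.
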