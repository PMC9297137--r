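# foodsignal

Census-tract food-desert analysis from geotagged food-related short texts.

Public-health researchers identify *food deserts* — census tracts that are
both **low-income** and **low-access** under the USDA Food Access Research
Atlas criteria — from surveys, store assessments, and GIS data. All of
these are slow and expensive. `foodsignal` implements an infodemiology
alternative: residents talk about food on social media, and the language
of those posts (which foods, with what sentiment, with what nutritional
profile) carries a tract-level signal about the local food environment.

The package is a complete, tested pipeline:

1. **Ingest** — read a geotagged post table (JSONL/CSV) and apply three
   filters: GPS coordinates required, promotional posts excluded by a
   hashtag blocklist (`#jobs`, `#hiring`, `#ad`), and at least one food
   keyword required.
2. **Match** — greedy longest-first multi-word keyword matching against a
   nutrient-annotated food lexicon (healthy / unhealthy / fast-food
   categories, 17 per-100 g nutrient fields). Phrases are matched longest
   first and consume their tokens, so "Burger King" is never also counted
   as "burger".
3. **Sentiment** — word-polarity scoring: each post's score is the sum of
   ±1 word polarities; the sign gives a positive/negative/neutral label,
   and six category-by-polarity flags are derived per post.
4. **Map** — point-to-bounding-box assignment of each post to a census
   tract (with true point-in-polygon as an alternative mode).
5. **Features** — aggregation to 28 tract-level features: six sentiment
   percentages, three mean mention counts, 17 mean per-item nutrient
   values, and healthy/unhealthy calorie means; merged with 12 ACS-style
   SES covariates and labeled by the USDA low-income/low-access rules.
6. **Screen** — one covariate-adjusted OLS model per feature,

   `y = β₀ + β_FD·x_FD + β₁x₁ + … + β₁₂x₁₂ + ε`,

   with the food-desert indicator as treatment and the 12 SES covariates
   as controls; features with two-sided p < α are flagged.
7. **Benchmark** — five feature-set models (SES baseline; +nutrients;
   +sentiment; +both; +screen-significant features) × four classifiers
   (adaptive boosting of decision stumps, gradient-boosted trees,
   logistic regression, and a stacked logistic ensemble), with min-max
   normalization fit on the training rows, a stratified 70:30 split,
   5-fold CV for hyperparameter selection, and held-out AUC per cell.

Because raw geotagged corpora cannot be redistributed, a first-class
**synthetic-data generator** emulates every input — grid tract
geometries, SES tables with exact food-desert prevalence, both lexicons,
and tweet corpora with a configurable effect structure implanted at the
sampling-probability level — so the entire chain is testable offline.

## Worked example

```r
library(foodsignal)

study <- generate_study(synthetic_config(n_tracts = 400, seed = 42))
study$lexicons$food
#> <food_lexicon> 42 entries ( healthy: 16, unhealthy: 16, fastfood: 10 )

match_foods("Craving Burger King and a burger with fries",
            study$lexicons$food)[1:4]
#>        keyword  category start end
#> 33 burger king  fastfood     2   3
#> 17      burger unhealthy     6   6
#> 19       fries unhealthy     8   8

res <- run_pipeline(study$corpus, study$tracts, study$ses,
                    study$lexicons$food, study$lexicons$sentiment,
                    seed = 42, benchmark = FALSE)
res$counts
#>             raw      geolocated non_promotional    food_related
#>            1880            1828            1776            1724
res$screen
#> <association_screen> 28 features; 8 significant at alpha = 0.05
#>    pct_unhealthy_pos, mean_unhealthy_mentions, mean_cholesterol, mean_fat,
#>    mean_potassium, mean_saturated_fatty_acids, mean_trans_fatty_acids,
#>    mean_vitamin_c
```

The filter chain drops 52 non-geolocated, 52 promotional, and 52
non-food posts, leaving 1724 food-related posts across 310 analyzed
tracts (25 of them food deserts). The screen recovers the implanted
structure: more unhealthy mentions, higher cholesterol, and lower
potassium per mentioned food item in food-desert tracts (the extra
nutrient hits are correlated side effects of the keyword tilt).

```r
bench <- run_benchmark(res$table, seed = 42, screen = res$screen,
                       methods = "gradient_boosting", models = c(1, 3, 4))
bench
#>              method model_id   auc delta_vs_baseline seed
#> 1 gradient_boosting        1 0.879            0.0000   42
#> 2 gradient_boosting        3 0.908            0.0286   42
#> 3 gradient_boosting        4 0.970            0.0908   42
```

Adding ingestion-language features to the SES baseline raises held-out
AUC — the direction the method is designed to demonstrate.

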