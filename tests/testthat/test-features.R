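# A hand-built profile frame for aggregation tests.
toy_profiles <- function() {
  lex <- tiny_lexicon()
  slex <- tiny_sentiment()
  corpus <- make_corpus(c("love my burger and fries",   # pos, unhealthy x2
                          "apple",                      # neutral, healthy
                          "hate this burger king",      # neg, fastfood
                          "great apple great",          # pos, healthy
                          "fries"),                     # neutral, unhealthy
                        id = sprintf("p%d", 1:5))
  profile_corpus(corpus, lex, slex)
}

test_that("tract aggregation produces percentages, means, and conservation", {
  prof <- toy_profiles()
  mapping <- data.frame(tweet_id = sprintf("p%d", 1:5),
                        tract_id = c("T1", "T1", "T1", "T1", "T2"))
  feats <- aggregate_tract_features(prof, mapping)
  expect_equal(nrow(feats), 2)
  t1 <- feats[feats$tract_id == "T1", ]
  expect_equal(t1$n_tweets, 4)
  # 1 of 4 tweets healthy+positive, neutral tweets count in the denominator
  expect_equal(t1$pct_healthy_pos, 25)
  expect_equal(t1$pct_unhealthy_pos, 25)
  expect_equal(t1$pct_fastfood_neg, 25)
  expect_equal(t1$pct_healthy_neg, 0)
  # per-tweet unhealthy counts {2,0,0,0} -> mean 0.5
  expect_equal(t1$mean_unhealthy_mentions, 0.5)
  # available-case tract nutrient mean: per-tweet cholesterol means are
  # {27, 0, NA, 0} -> 9
  expect_equal(t1$mean_cholesterol, 9)
  # conservation and range invariants
  expect_equal(sum(feats$n_tweets), nrow(mapping))
  pct <- unlist(feats[feature_names()$sentiment])
  expect_true(all(pct >= 0 & pct <= 100))
  for (cc in c("healthy", "unhealthy", "fastfood")) {
    expect_true(all(feats[[paste0("pct_", cc, "_pos")]] +
                      feats[[paste0("pct_", cc, "_neg")]] <= 100))
  }
})

test_that("aggregation drops unmapped tweets and rejects unknown tracts", {
  prof <- toy_profiles()
  mapping <- data.frame(tweet_id = sprintf("p%d", 1:4),
                        tract_id = rep("T1", 4))
  feats <- aggregate_tract_features(prof, mapping)
  expect_equal(feats$n_tweets, 4)  # p5 unmapped, dropped
  expect_error(
    aggregate_tract_features(prof, mapping, tract_ids = c("T9")),
    "unknown tract")
})

test_that("SES merge is an inner join that flags duplicates", {
  feats <- data.frame(tract_id = c("T1", "T2", "T3"), n_tweets = 1:3)
  ses <- data.frame(tract_id = c("T1", "T2"), population = c(100, 200))
  merged <- merge_ses(feats, ses)
  expect_equal(nrow(merged), 2)
  expect_equal(attr(merged, "n_dropped"), 1)
  expect_error(merge_ses(feats, rbind(ses, ses[1, ])), "duplicate")
})

test_that("USDA labeling applies inclusive low-income/low-access criteria", {
  base <- data.frame(
    tract_id = "T", pct_below_poverty = 10, median_family_income = 90000,
    state_median_family_income = 100000, metro_median_family_income = NA,
    n_low_access = 0, pct_low_access = 0)
  # poverty 25 + access 40% -> desert via poverty20 and access33pct
  a <- base; a$pct_below_poverty <- 25; a$pct_low_access <- 40
  la <- label_food_desert(a)
  expect_true(la$is_food_desert && la$poverty20 && la$access33pct)
  expect_false(la$income80_state)
  # low access but not low income -> not a desert
  b <- base; b$n_low_access <- 600
  expect_false(label_food_desert(b)$is_food_desert)
  expect_true(label_food_desert(b)$low_access)
  # boundaries inclusive: income exactly 80% of state, exactly 500 people
  c0 <- base; c0$median_family_income <- 80000; c0$n_low_access <- 500
  lc <- label_food_desert(c0)
  expect_true(lc$is_food_desert && lc$income80_state && lc$access500)
  # metro criterion only when a metro income is present
  d <- base; d$metro_median_family_income <- 120000; d$n_low_access <- 500
  expect_true(label_food_desert(d)$income80_metro)
  expect_true(label_food_desert(d)$is_food_desert)
  expect_error(label_food_desert(transform(base, n_low_access = -1)),
               "negative")
})

test_that("labeling is monotone in poverty and access", {
  set.seed(13)
  for (i in 1:50) {
    row <- data.frame(
      tract_id = "T",
      pct_below_poverty = runif(1, 0, 40),
      median_family_income = runif(1, 30000, 150000),
      state_median_family_income = 75000,
      metro_median_family_income = sample(c(NA, 78000), 1),
      n_low_access = sample(0:1000, 1),
      pct_low_access = runif(1, 0, 60))
    l0 <- label_food_desert(row)
    up <- row
    up$pct_below_poverty <- row$pct_below_poverty + runif(1, 0, 30)
    up$n_low_access <- row$n_low_access + sample(0:600, 1)
    l1 <- label_food_desert(up)
    expect_true(l1$is_food_desert >= l0$is_food_desert)
  }
})
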