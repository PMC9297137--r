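test_that("longest-first matching prevents sub-phrase double counting", {
  lex <- tiny_lexicon()
  m <- match_foods("Craving Burger King tonight", lex)
  expect_equal(m$keyword, "burger king")

  m2 <- match_foods("Burger King burger", lex)
  expect_equal(m2$keyword, c("burger king", "burger"))

  m3 <- match_foods("burger burger", lex)
  expect_equal(m3$keyword, c("burger", "burger"))

  expect_equal(nrow(match_foods("soup or salad", lex)), 0)

  # three-word phrase over its one-word suffix
  m4 <- match_foods("that red velvet cake was cake heaven", lex)
  expect_equal(m4$keyword, c("red velvet cake", "cake"))
})

test_that("matching is invariant to case, whitespace, and handles plurals", {
  lex <- tiny_lexicon()
  a <- match_foods("BURGER   king and FRIES", lex)
  b <- match_foods("burger king and fries", lex)
  expect_equal(a$keyword, b$keyword)
  expect_equal(match_foods("two burgers please", lex)$keyword, "burger")
  expect_equal(nrow(match_foods("two burgers please", lex,
                                plural_fold = FALSE)), 0)
})

test_that("matched spans never overlap", {
  lex <- generate_lexicons(synthetic_config(seed = 2))$food
  texts <- c("burger king burger fries pizza hut pizza",
             "double cheeseburger cheeseburger burger",
             "jack in the box fries and a hot dog",
             "sweet potato fries with greek yogurt")
  for (tx in texts) {
    m <- match_foods(tx, lex)
    spans <- unlist(mapply(seq, m$start, m$end, SIMPLIFY = FALSE))
    expect_equal(anyDuplicated(spans), 0)
  }
})

test_that("matcher agrees with the exhaustive longest-first oracle", {
  set.seed(11)
  vocab <- c("a", "b", "c", "d", "e", "f")
  for (i in 1:300) {
    n_kw <- sample(1:6, 1)
    kws <- unique(vapply(seq_len(n_kw), function(j) {
      paste(sample(vocab, sample(1:3, 1), replace = TRUE), collapse = " ")
    }, character(1)))
    lex <- make_lexicon(data.frame(
      keyword = kws, category = sample(c("healthy", "unhealthy"),
                                       length(kws), replace = TRUE)))
    text <- paste(sample(vocab, sample(1:12, 1), replace = TRUE),
                  collapse = " ")
    got <- match_foods(text, lex)
    want <- oracle_match(text, lex$entries$keyword)
    expect_equal(got$keyword, want$keyword, info = text)
    expect_equal(got$start, want$start, info = text)
  }
})

test_that("score_tweet averages nutrients available-case", {
  lex <- tiny_lexicon()
  # cholesterol 54 (burger) and 0 (fries) -> mean 27
  m <- match_foods("burger and fries", lex)
  p <- score_tweet("t1", m)
  expect_equal(p$mean_cholesterol, 27)
  expect_equal(p$n_unhealthy, 2)
  # single item: profile equals that item's vector
  p1 <- score_tweet("t2", match_foods("apple", lex))
  expect_equal(p1$mean_calories, 52)
  expect_equal(p1$mean_potassium, 107)
  # nutrient present for only one of two matches: mean over the one
  m2 <- match_foods("burger king fries", lex)  # brand has no nutrients
  p2 <- score_tweet("t3", m2)
  expect_equal(p2$mean_potassium, 451)
  expect_equal(p2$n_fastfood, 1)
  # zero matches: counts 0, all nutrients missing
  p0 <- score_tweet("t0", match_foods("nothing here", lex))
  expect_equal(p0$n_matches, 0)
  expect_true(is.na(p0$mean_calories))
})

test_that("nutrient means stay within the contributing items' range", {
  lex <- generate_lexicons(synthetic_config(seed = 3))$food
  set.seed(5)
  kws <- lex$entries$keyword
  for (i in 1:50) {
    text <- paste(sample(kws, sample(2:4, 1)), collapse = " and ")
    m <- match_foods(text, lex)
    p <- score_tweet("t", m)
    for (nm in feature_names()$nutrient_fields) {
      v <- m[[nm]]
      if (all(is.na(v))) {
        expect_true(is.na(p[[paste0("mean_", nm)]]))
      } else {
        expect_gte(p[[paste0("mean_", nm)]], min(v, na.rm = TRUE))
        expect_lte(p[[paste0("mean_", nm)]], max(v, na.rm = TRUE))
      }
    }
  }
})

test_that("profile_corpus profiles each tweet and enforces its precondition", {
  lex <- tiny_lexicon()
  slex <- tiny_sentiment()
  corpus <- make_corpus(c("love my burger king", "apple a day",
                          "hate these fries"))
  prof <- profile_corpus(corpus, lex, slex)
  expect_equal(nrow(prof), 3)
  expect_true(all(prof$n_matches >= 1))
  expect_equal(prof$sentiment_label, c("positive", "neutral", "negative"))
  expect_true(prof$fastfood_pos[1])
  expect_true(prof$unhealthy_neg[3])

  # matches the per-tweet scorer exactly
  p1 <- score_tweet(corpus$id[1], match_foods(corpus$text[1], lex))
  expect_equal(prof[1, names(p1)], p1)

  bad <- make_corpus(c("apple", "no food here"))
  expect_error(profile_corpus(bad, lex), "no food keyword match")
  expect_equal(nrow(profile_corpus(make_corpus(character(0)), lex)), 0)
})
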