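test_that("one seed fixes the whole synthetic study", {
  a <- generate_study(synthetic_config(n_tracts = 60, seed = 12))
  b <- generate_study(synthetic_config(n_tracts = 60, seed = 12))
  expect_identical(a, b)
  c0 <- generate_study(synthetic_config(n_tracts = 60, seed = 13))
  expect_false(identical(a$corpus$text, c0$corpus$text))
})

test_that("constructed desert tracts round-trip through the USDA labeler", {
  cfg <- synthetic_config(n_tracts = 400, food_desert_fraction = 0.1,
                          seed = 6)
  tr <- generate_tracts(cfg)
  labels <- label_food_desert(tr$ses)
  expect_equal(sum(labels$is_food_desert), 40)
  expect_equal(labels$is_food_desert, tr$is_desert)

  none <- generate_tracts(synthetic_config(n_tracts = 100,
                                           food_desert_fraction = 0, seed = 6))
  expect_equal(sum(label_food_desert(none$ses)$is_food_desert), 0)
})

test_that("generated tract squares are disjoint with unit bboxes", {
  tr <- generate_tracts(synthetic_config(n_tracts = 30, seed = 2))$tracts
  expect_true(all(tr$bbox_area == 1))
  corners <- paste(tr$min_lon, tr$min_lat)
  expect_equal(anyDuplicated(corners), 0)
})

test_that("fixture lexicons load and contain the nested-phrase pattern", {
  lx <- generate_lexicons(synthetic_config(seed = 3))
  v <- validate_lexicon(lx$food)
  expect_true(all(v$category_counts > 0))
  # multi-word keyword whose sub-phrase is also a keyword
  kws <- lx$food$entries$keyword
  multi <- kws[lx$food$entries$n_words > 1]
  has_nested <- any(vapply(multi, function(k) {
    parts <- strsplit(k, " ")[[1]]
    any(parts %in% kws) ||
      any(vapply(seq_len(length(parts) - 1), function(i) {
        paste(parts[(i + 1):length(parts)], collapse = " ") %in% kws ||
          paste(parts[1:i], collapse = " ") %in% kws
      }, logical(1)))
  }, logical(1)))
  expect_true(has_nested)
  # fast-food brands carry no nutrient profile
  ff <- lx$food$entries[lx$food$entries$category == "fastfood", ]
  expect_true(all(is.na(ff$calories)))
  expect_identical(lx$food, generate_lexicons(synthetic_config(seed = 3))$food)
})

test_that("injected tweets exercise each ingest filter by construction", {
  st <- generate_study(synthetic_config(n_tracts = 80, seed = 5))
  kind <- st$truth$kind
  geo <- filter_geolocated(st$corpus)
  expect_false(any(kind[geo$id] == "nongeo"))
  promo_free <- filter_promotional(st$corpus)
  expect_false(any(kind[promo_free$id] == "promo"))
  expect_true(all(names(kind)[kind == "promo"] %in%
                    setdiff(st$corpus$id, promo_free$id)))
  food <- filter_food_related(st$corpus, st$lexicons$food)
  expect_false(any(kind[food$id] == "nonfood"))
  # signal tweets survive every filter
  chain <- filter_food_related(filter_promotional(filter_geolocated(
    st$corpus)), st$lexicons$food)
  expect_setequal(chain$id, names(kind)[kind == "signal"])
})

test_that("implanted effects move tract means in the configured directions", {
  st <- generate_study(synthetic_config(n_tracts = 500, seed = 10))
  res <- run_pipeline(st$corpus, st$tracts, st$ses, st$lexicons$food,
                      st$lexicons$sentiment, benchmark = FALSE)
  tab <- res$table
  fd <- tab$is_food_desert
  expect_gt(mean(tab$mean_cholesterol[fd], na.rm = TRUE),
            mean(tab$mean_cholesterol[!fd], na.rm = TRUE))
  expect_lt(mean(tab$mean_potassium[fd], na.rm = TRUE),
            mean(tab$mean_potassium[!fd], na.rm = TRUE))
  expect_gt(mean(tab$mean_unhealthy_mentions[fd]),
            mean(tab$mean_unhealthy_mentions[!fd]))
  expect_gt(mean(tab$pct_healthy_pos[fd]), mean(tab$pct_healthy_pos[!fd]))
  expect_gt(mean(tab$pct_fastfood_pos[fd]), mean(tab$pct_fastfood_pos[!fd]))
})

test_that("study files round-trip through the standard loaders", {
  st <- generate_study(synthetic_config(n_tracts = 40, seed = 21))
  dir <- tempfile()
  write_study_files(st, dir)
  corpus <- read_tweets(file.path(dir, "tweets.jsonl"))
  expect_equal(nrow(corpus), nrow(st$corpus))
  expect_equal(corpus$text, st$corpus$text)
  expect_equal(corpus$lat, st$corpus$lat)
  tracts <- load_tracts(file.path(dir, "tracts.geojson"))
  expect_equal(tracts$tract_id, st$tracts$tract_id)
  expect_equal(tracts$min_lon, st$tracts$min_lon)
  food <- load_food_lexicon(file.path(dir, "food_lexicon.csv"))
  expect_equal(food$entries, st$lexicons$food$entries)
  slex <- load_sentiment_lexicon(file.path(dir, "sentiment_lexicon.csv"))
  expect_identical(slex, st$lexicons$sentiment)
  ses <- read.csv(file.path(dir, "ses.csv"),
                  colClasses = c(tract_id = "character"))
  expect_equal(ses$pct_below_poverty, st$ses$pct_below_poverty)
})
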