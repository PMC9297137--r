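#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator. The defaults are the
#' study conditions the pipeline is tested under: food-desert prevalence
#' 7.52%, a negative-binomial tweets-per-tract distribution whose
#' conditional-on-observed median is 4, and an implanted effect block whose
#' signs match the five associations the screening stage is expected to
#' recover (more unhealthy mentions, more positive healthy and fast-food
#' sentiment, higher cholesterol and lower potassium per mentioned item in
#' food-desert tracts).
#'
#' @param n_tracts Number of unit-square census tracts laid out on a grid.
#' @param food_desert_fraction Fraction of tracts constructed to satisfy
#'   the USDA low-income/low-access criteria (default 0.0752).
#' @param tweets_nb_size,tweets_nb_mu Negative-binomial size and mean for
#'   tweets per tract (defaults give median 4, IQR 7 among tracts with at
#'   least one tweet).
#' @param delta_pct_healthy_pos,delta_pct_fastfood_pos Added probability
#'   (on the 0-1 scale) that a desert tweet mentioning the category also
#'   carries a positive polarity word.
#' @param delta_mean_unhealthy_mentions Probability that a desert tweet
#'   receives one extra unhealthy food mention.
#' @param delta_cholesterol,delta_potassium Exponential-tilt log-weights
#'   (per within-category SD of the nutrient) applied to keyword sampling
#'   in desert tracts; positive values favor keywords high in the
#'   nutrient.
#' @param base_pos,base_neg Baseline probabilities that a tweet carries a
#'   positive / negative polarity word.
#' @param category_probs Baseline healthy/unhealthy/fastfood mention
#'   probabilities (length 3, summing to 1).
#' @param promo_fraction,nongeo_fraction,nonfood_fraction Fractions of
#'   extra injected tweets that are promotional, missing coordinates, or
#'   free of food keywords, exercising the three ingest filters.
#' @param state_median_income,metro_median_income State and metro median
#'   family incomes used by the USDA labeling inputs.
#' @param metro_missing_fraction Fraction of tracts outside a metro area
#'   (missing metro income).
#' @param seed Integer seed fixing every draw.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_tracts = 500,
                             food_desert_fraction = 0.0752,
                             tweets_nb_size = 0.7,
                             tweets_nb_mu = 5,
                             delta_pct_healthy_pos = 0.30,
                             delta_pct_fastfood_pos = 0.40,
                             delta_mean_unhealthy_mentions = 0.35,
                             delta_cholesterol = 1.0,
                             delta_potassium = -1.0,
                             base_pos = 0.35,
                             base_neg = 0.25,
                             category_probs = c(healthy = 0.40,
                                                unhealthy = 0.40,
                                                fastfood = 0.20),
                             promo_fraction = 0.03,
                             nongeo_fraction = 0.03,
                             nonfood_fraction = 0.03,
                             state_median_income = 75000,
                             metro_median_income = 78000,
                             metro_missing_fraction = 0.3,
                             seed = 1) {
  stopifnot(n_tracts >= 1,
            food_desert_fraction >= 0, food_desert_fraction <= 1,
            tweets_nb_size > 0, tweets_nb_mu > 0,
            base_pos >= 0, base_neg >= 0, base_pos + base_neg <= 1,
            length(category_probs) == 3, all(category_probs >= 0),
            abs(sum(category_probs) - 1) < 1e-8,
            delta_mean_unhealthy_mentions >= 0,
            delta_mean_unhealthy_mentions <= 1,
            is.finite(delta_pct_healthy_pos), is.finite(delta_pct_fastfood_pos),
            is.finite(delta_cholesterol), is.finite(delta_potassium))
  grid_cols <- ceiling(sqrt(n_tracts))
  grid_rows <- ceiling(n_tracts / grid_cols)
  if (grid_rows > 89 || grid_cols > 179) {
    stop("n_tracts too large for a unit-degree grid inside valid coordinates")
  }
  structure(
    list(n_tracts = n_tracts, grid_rows = grid_rows, grid_cols = grid_cols,
         food_desert_fraction = food_desert_fraction,
         tweets_nb_size = tweets_nb_size, tweets_nb_mu = tweets_nb_mu,
         delta_pct_healthy_pos = delta_pct_healthy_pos,
         delta_pct_fastfood_pos = delta_pct_fastfood_pos,
         delta_mean_unhealthy_mentions = delta_mean_unhealthy_mentions,
         delta_cholesterol = delta_cholesterol,
         delta_potassium = delta_potassium,
         base_pos = base_pos, base_neg = base_neg,
         category_probs = category_probs,
         promo_fraction = promo_fraction,
         nongeo_fraction = nongeo_fraction,
         nonfood_fraction = nonfood_fraction,
         state_median_income = state_median_income,
         metro_median_income = metro_median_income,
         metro_missing_fraction = metro_missing_fraction,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate synthetic census tracts and their SES table
#'
#' Lays out `n_tracts` disjoint unit squares on a grid (so bounding-box and
#' polygon assignment agree and prevalence arithmetic is exact), draws SES
#' covariates near published tract-level means and SDs, and constructs the
#' USDA labeling inputs so that exactly `round(n_tracts *
#' food_desert_fraction)` tracts satisfy the low-income and low-access
#' criteria (high poverty plus high low-access share) while every other
#' tract fails the low-access arm.
#'
#' @param cfg A `synthetic_config`.
#' @return A list with `tracts` (a `tract_set`), `ses` (the SES/labeling
#'   data.frame), and `is_desert` (logical vector over tracts).
#' @export
generate_tracts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_tracts
  n_desert <- round(n * cfg$food_desert_fraction)
  idx <- seq_len(n) - 1L
  col <- idx %% cfg$grid_cols
  row <- idx %/% cfg$grid_cols
  tract_id <- sprintf("T%05d", seq_len(n))
  rings <- lapply(seq_len(n), function(i) {
    x0 <- col[i]; y0 <- row[i]
    list(cbind(c(x0, x0 + 1, x0 + 1, x0, x0),
               c(y0, y0, y0 + 1, y0 + 1, y0)))
  })
  tracts <- data.frame(tract_id = tract_id,
                       min_lon = col, min_lat = row,
                       max_lon = col + 1, max_lat = row + 1,
                       bbox_area = 1, stringsAsFactors = FALSE)
  tracts$rings <- rings
  class(tracts) <- c("tract_set", "data.frame")

  trunc_norm <- function(n, mean, sd, lo = 0, hi = Inf) {
    pmin(pmax(rnorm(n, mean, sd), lo), hi)
  }
  is_desert <- rep(FALSE, n)
  if (n_desert > 0) is_desert[sample.int(n, n_desert)] <- TRUE

  population <- round(trunc_norm(n, 4283, 2244, lo = 200))
  housing <- round(trunc_norm(n, 1788, 864, lo = 100))
  households <- round(housing * runif(n, 0.85, 0.98))
  ses <- data.frame(
    tract_id = tract_id,
    pct_white_nonhispanic = trunc_norm(n, 62.7, 23.4, 0, 100),
    pct_black = trunc_norm(n, 15.6, 21.0, 0, 100),
    pct_other_race = trunc_norm(n, 8.9, 12.3, 0, 100),
    pct_asian = trunc_norm(n, 7.4, 9.2, 0, 100),
    pct_aian = trunc_norm(n, 1.0, 1.9, 0, 100),
    pct_owner_occupied = trunc_norm(n, 49.3, 24.8, 0, 100),
    pct_below_poverty = trunc_norm(n, 16.2, 12.1, 0, 60),
    n_housing_units = housing,
    n_households = households,
    median_family_income = trunc_norm(n, 82371, 42680, lo = 10000),
    median_age = trunc_norm(n, 37.0, 6.8, lo = 18),
    population = population,
    state_median_family_income = cfg$state_median_income,
    metro_median_family_income = ifelse(
      runif(n) < cfg$metro_missing_fraction, NA_real_,
      cfg$metro_median_income),
    stringsAsFactors = FALSE
  )
  # construct the labeling inputs: deserts satisfy poverty >= 20 and
  # low-access share >= 33; every other tract fails both access criteria
  ses$pct_below_poverty[is_desert] <- runif(n_desert, 22, 45)
  ses$pct_low_access <- runif(n, 0, 30)
  ses$pct_low_access[is_desert] <- runif(n_desert, 35, 70)
  ses$n_low_access <- pmin(round(population * ses$pct_low_access / 100), 449)
  ses$n_low_access[is_desert] <-
    round(population[is_desert] * ses$pct_low_access[is_desert] / 100)
  list(tracts = tracts, ses = ses, is_desert = is_desert)
}

# ---- lexicon fixtures ----------------------------------------------------

healthy_base <- function() {
  data.frame(
    keyword = c("apple", "banana", "kale", "spinach", "quinoa", "oatmeal",
                "broccoli", "carrot", "avocado", "almond", "hummus",
                "blueberry", "greek yogurt", "brown rice", "sweet potato",
                "grilled chicken salad"),
    calories = c(52, 89, 49, 23, 120, 71, 34, 41, 160, 579, 166, 57, 59,
                 111, 86, 120),
    cholesterol = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 10, 0, 0, 60),
    potassium = c(107, 358, 491, 558, 172, 70, 316, 320, 485, 733, 228, 77,
                  141, 43, 337, 250),
    stringsAsFactors = FALSE
  )
}

unhealthy_base <- function() {
  data.frame(
    keyword = c("burger", "cheeseburger", "fries", "pizza", "donut",
                "cupcake", "milkshake", "bacon", "soda", "candy", "nachos",
                "hot dog", "ice cream", "fried chicken",
                "double cheeseburger", "red velvet cake"),
    calories = c(254, 303, 312, 266, 452, 305, 112, 541, 41, 535, 306, 290,
                 207, 246, 282, 367),
    cholesterol = c(54, 85, 0, 17, 19, 55, 40, 110, 0, 8, 35, 60, 44, 113,
                    100, 65),
    potassium = c(198, 188, 451, 172, 201, 98, 183, 565, 2, 140, 172, 166,
                  199, 234, 190, 105),
    stringsAsFactors = FALSE
  )
}

fastfood_keywords <- function() {
  c("burger king", "taco bell", "dairy queen", "del taco", "pizza hut",
    "mcdonalds", "kfc", "popeyes", "whataburger", "jack in the box")
}

positive_words <- function() {
  c("love", "delicious", "great", "tasty", "amazing", "awesome", "yummy",
    "fresh", "perfect", "happy", "best", "enjoy", "wonderful", "fantastic",
    "good", "excellent", "divine", "delightful", "savory", "satisfying",
    "superb", "heavenly", "glorious", "scrumptious", "favorite",
    "incredible", "lovely", "brilliant", "joyful", "blissful")
}

negative_words <- function() {
  c("hate", "awful", "gross", "terrible", "disgusting", "bad", "worst",
    "nasty", "bland", "stale", "soggy", "horrible", "dreadful", "vile",
    "rotten", "greasy", "burnt", "disappointing", "sad", "angry", "yuck",
    "inedible", "foul", "lousy", "unpleasant", "miserable", "revolting",
    "dismal", "icky", "grim")
}

filler_words <- function() {
  c("just", "today", "tonight", "lunch", "dinner", "breakfast", "went",
    "got", "having", "time", "later", "downtown", "about", "really",
    "some", "more", "with", "friends", "again", "maybe", "weekend",
    "morning", "after", "place", "spot", "little", "finally", "waiting",
    "trying", "around")
}

#' Generate the fixture food and sentiment lexicons
#'
#' Builds a 42-entry food lexicon (16 healthy, 16 unhealthy, 10 fast-food
#' brand names, including multi-word phrases whose sub-phrases are also
#' keywords, such as "double cheeseburger"/"cheeseburger"/"burger" and
#' "pizza hut"/"pizza") with per-100 g nutrient profiles: calories,
#' cholesterol, and potassium are fixed realistic values (healthy entries
#' low-cholesterol/high-potassium, unhealthy the reverse, so implanted
#' nutrient effects are expressible), the remaining nutrients are drawn
#' once from category-plausible ranges under the config seed, and
#' fast-food brands carry no nutrient profile. The polarity lexicon has 30
#' positive and 30 negative words.
#'
#' @param cfg A `synthetic_config`.
#' @return A list with `food` (a `food_lexicon`) and `sentiment` (a
#'   `sentiment_lexicon`).
#' @export
generate_lexicons <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  h <- healthy_base(); u <- unhealthy_base(); f <- fastfood_keywords()
  draw <- function(n, lo, hi, digits = 1) round(runif(n, lo, hi), digits)
  nh <- nrow(h); nu <- nrow(u); nf <- length(f)
  nut <- function(cal, chol, pot, calcium, carbs, fat, fiber, iron, protein,
                  satfa, sodium, sugar, transfa, unsatfa, vita, vitc) {
    data.frame(calories = cal, calcium = calcium, carbohydrates = carbs,
               cholesterol = chol, energy = round(cal * 4.184, 1), fat = fat,
               fiber = fiber, iron = iron, potassium = pot, protein = protein,
               saturated_fatty_acids = satfa, sodium = sodium, sugar = sugar,
               trans_fatty_acids = transfa,
               unsaturated_fatty_acids = unsatfa, vitamin_a = vita,
               vitamin_c = vitc)
  }
  h_nut <- nut(h$calories, h$cholesterol, h$potassium,
               draw(nh, 10, 150), draw(nh, 5, 30), draw(nh, 0, 5),
               draw(nh, 1, 5), draw(nh, 0.2, 2), draw(nh, 0.5, 5),
               draw(nh, 0, 1), draw(nh, 1, 80), draw(nh, 2, 15),
               rep(0, nh), draw(nh, 0, 3), draw(nh, 50, 800),
               draw(nh, 5, 60))
  u_nut <- nut(u$calories, u$cholesterol, u$potassium,
               draw(nu, 20, 200), draw(nu, 20, 60), draw(nu, 10, 35),
               draw(nu, 0, 2), draw(nu, 0.5, 4), draw(nu, 5, 20),
               draw(nu, 3, 12), draw(nu, 200, 1200), draw(nu, 5, 40),
               draw(nu, 0, 1.5), draw(nu, 2, 12), draw(nu, 0, 300),
               draw(nu, 0, 5))
  f_nut <- as.data.frame(setNames(rep(list(rep(NA_real_, nf)), 17),
                                  NUTRIENT_FIELDS))
  food <- new_food_lexicon(
    keyword = c(h$keyword, u$keyword, f),
    category = rep(c("healthy", "unhealthy", "fastfood"), c(nh, nu, nf)),
    nutrients = rbind(h_nut[NUTRIENT_FIELDS], u_nut[NUTRIENT_FIELDS], f_nut)
  )
  sentiment <- new_sentiment_lexicon(
    word = c(positive_words(), negative_words()),
    polarity = rep(c("positive", "negative"), each = 30)
  )
  list(food = food, sentiment = sentiment)
}

# Per-category keyword sampling weights under the desert exponential tilt:
# log-weight = delta_cholesterol * z(cholesterol) + delta_potassium *
# z(potassium), z standardized within category (uniform where the nutrient
# is missing or constant, e.g. fast-food brands).
tilt_weights <- function(lex, cfg) {
  e <- lex$entries
  lapply(setNames(FOOD_CATEGORIES, FOOD_CATEGORIES), function(cc) {
    rows <- which(e$category == cc)
    z <- function(v) {
      if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0) {
        rep(0, length(v))
      } else {
        as.numeric(scale(v))
      }
    }
    lw <- cfg$delta_cholesterol * z(e$cholesterol[rows]) +
      cfg$delta_potassium * z(e$potassium[rows])
    lw[is.na(lw)] <- 0
    w <- exp(lw)
    list(rows = rows, base = rep(1 / length(rows), length(rows)),
         desert = w / sum(w))
  })
}

#' Generate a geotagged synthetic tweet corpus
#'
#' Draws a tweets-per-tract count for every tract, assembles each tweet's
#' text from filler words, 1-3 food keywords, and at most one polarity
#' word, and places it uniformly inside its tract square. Effects are
#' implanted at the sampling-probability level in food-desert tracts only:
#' an extra unhealthy mention with probability
#' `delta_mean_unhealthy_mentions`, a boosted positive-word probability
#' for tweets mentioning healthy foods or fast-food restaurants, and
#' keyword choice tilted toward high-cholesterol/low-potassium items —
#' so the aggregated tract features carry the signal only if every
#' pipeline stage transmits it. Extra promotional, non-geolocated, and
#' non-food tweets are injected to exercise the ingest filters.
#'
#' @param cfg A `synthetic_config`.
#' @param tracts Output of [generate_tracts()].
#' @param lexicons Output of [generate_lexicons()].
#' @return A list with `corpus` (a `tweet_corpus`) and `truth` (a list
#'   recording tweet kinds, tract assignments, desert flags, and the
#'   config).
#' @export
generate_tweets <- function(cfg, tracts, lexicons) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lex <- lexicons$food
  if (nrow(lex$entries) == 0) stop("empty food lexicon")
  set.seed(cfg$seed + 2L)
  n_tr <- nrow(tracts$tracts)
  counts <- rnbinom(n_tr, size = cfg$tweets_nb_size, mu = cfg$tweets_nb_mu)
  N <- sum(counts)
  if (N == 0) stop("no tweets drawn; increase tweets_nb_mu or n_tracts")
  tract_of <- rep(seq_len(n_tr), counts)
  desert <- tracts$is_desert[tract_of]

  e <- lex$entries
  tw <- tilt_weights(lex, cfg)
  # items per tweet: 1-3 baseline plus a possible extra unhealthy mention
  n_items <- 1L + rbinom(N, 2, 0.2)
  extra_unhealthy <- desert & runif(N) < cfg$delta_mean_unhealthy_mentions
  item_tweet <- rep(seq_len(N), n_items)
  M <- length(item_tweet)
  cat_draw <- sample(FOOD_CATEGORIES, M, replace = TRUE,
                     prob = cfg$category_probs)
  item_row <- integer(M)
  for (cc in FOOD_CATEGORIES) {
    for (dz in c(FALSE, TRUE)) {
      sel <- which(cat_draw == cc & desert[item_tweet] == dz)
      if (length(sel) == 0) next
      w <- if (dz) tw[[cc]]$desert else tw[[cc]]$base
      item_row[sel] <- sample(tw[[cc]]$rows, length(sel), replace = TRUE,
                              prob = w)
    }
  }
  ex_idx <- which(extra_unhealthy)
  if (length(ex_idx) > 0) {
    ex_rows <- sample(tw$unhealthy$rows, length(ex_idx), replace = TRUE,
                      prob = tw$unhealthy$desert)
    item_tweet <- c(item_tweet, ex_idx)
    item_row <- c(item_row, ex_rows)
    ord <- order(item_tweet)
    item_tweet <- item_tweet[ord]; item_row <- item_row[ord]
  }
  item_cat <- e$category[item_row]
  has_h <- tabulate(item_tweet[item_cat == "healthy"], N) > 0
  has_f <- tabulate(item_tweet[item_cat == "fastfood"], N) > 0

  p_pos <- pmin(cfg$base_pos + desert * (has_h * cfg$delta_pct_healthy_pos +
                                           has_f * cfg$delta_pct_fastfood_pos),
                0.92)
  u <- runif(N)
  word_kind <- ifelse(u < p_pos, "pos",
                      ifelse(u < p_pos + cfg$base_neg, "neg", "none"))
  sent_word <- character(N)
  sent_word[word_kind == "pos"] <- sample(positive_words(),
                                          sum(word_kind == "pos"), TRUE)
  sent_word[word_kind == "neg"] <- sample(negative_words(),
                                          sum(word_kind == "neg"), TRUE)

  # assemble text: each keyword phrase is an atomic unit; unit order is
  # random; some keywords get mixed case to exercise case-insensitivity
  kw <- e$keyword[item_row]
  upcase <- runif(length(kw)) < 0.2
  kw[upcase] <- gsub("\\b([a-z])", "\\U\\1", kw[upcase], perl = TRUE)
  kw_by_tweet <- split(kw, factor(item_tweet, levels = seq_len(N)))
  n_fill <- 2L + rbinom(N, 3, 0.5)
  fill_pool <- filler_words()
  texts <- vapply(seq_len(N), function(i) {
    units <- c(kw_by_tweet[[i]], sample(fill_pool, n_fill[i]))
    if (nzchar(sent_word[i])) units <- c(units, sent_word[i])
    paste(units[sample.int(length(units))], collapse = " ")
  }, character(1))

  lon <- tracts$tracts$min_lon[tract_of] + runif(N, 0.02, 0.98)
  lat <- tracts$tracts$min_lat[tract_of] + runif(N, 0.02, 0.98)

  # injected tweets exercising the filters
  n_promo <- ceiling(N * cfg$promo_fraction)
  n_nongeo <- ceiling(N * cfg$nongeo_fraction)
  n_nonfood <- ceiling(N * cfg$nonfood_fraction)
  promo_tags <- c("#hiring", "#jobs", "#ad")
  promo_text <- paste("now", sample(promo_tags, n_promo, TRUE),
                      "line cooks at the", sample(e$keyword, n_promo, TRUE),
                      "stand apply", sample(fill_pool, n_promo, TRUE))
  nongeo_text <- paste(sample(fill_pool, n_nongeo, TRUE),
                       sample(e$keyword, n_nongeo, TRUE),
                       sample(fill_pool, n_nongeo, TRUE))
  nonfood_text <- vapply(seq_len(n_nonfood), function(i) {
    paste(sample(fill_pool, 5), collapse = " ")
  }, character(1))
  rand_tract <- sample.int(n_tr, n_promo + n_nonfood, replace = TRUE)
  inj_lon <- tracts$tracts$min_lon[rand_tract] +
    runif(n_promo + n_nonfood, 0.02, 0.98)
  inj_lat <- tracts$tracts$min_lat[rand_tract] +
    runif(n_promo + n_nonfood, 0.02, 0.98)

  n_all <- N + n_promo + n_nongeo + n_nonfood
  kind <- rep(c("signal", "promo", "nongeo", "nonfood"),
              c(N, n_promo, n_nongeo, n_nonfood))
  df <- data.frame(
    id = sprintf("t%07d", seq_len(n_all)),
    user_id = sprintf("u%05d", sample.int(max(2, ceiling(n_all / 3)),
                                          n_all, replace = TRUE)),
    timestamp = format(
      as.POSIXct("2020-03-01 00:00:00", tz = "UTC") +
        round(runif(n_all, 0, 275 * 86400)),
      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    text = c(texts, promo_text, nongeo_text, nonfood_text),
    lat = c(lat, inj_lat[seq_len(n_promo)], rep(NA_real_, n_nongeo),
            inj_lat[n_promo + seq_len(n_nonfood)]),
    lon = c(lon, inj_lon[seq_len(n_promo)], rep(NA_real_, n_nongeo),
            inj_lon[n_promo + seq_len(n_nonfood)]),
    stringsAsFactors = FALSE
  )
  shuffle <- sample.int(n_all)
  df <- df[shuffle, , drop = FALSE]
  rownames(df) <- NULL
  truth <- list(
    kind = setNames(kind[shuffle], df$id),
    tract_id = setNames(c(tracts$tracts$tract_id[tract_of],
                          rep(NA_character_, n_promo + n_nongeo + n_nonfood)
                          )[shuffle], df$id),
    is_desert_tract = tracts$is_desert,
    n_signal = N,
    config = unclass(cfg)
  )
  list(corpus = new_tweet_corpus(df, source = "synthetic"), truth = truth)
}

#' Generate a complete synthetic study
#'
#' One call producing every pipeline input under a single seed: tract
#' geometries, the SES table, both lexicons, and the tweet corpus with its
#' ground truth.
#'
#' @param cfg A `synthetic_config`.
#' @return A list with `tracts`, `ses`, `is_desert`, `lexicons`, `corpus`,
#'   and `truth`.
#' @export
generate_study <- function(cfg = synthetic_config()) {
  tr <- generate_tracts(cfg)
  lx <- generate_lexicons(cfg)
  tws <- generate_tweets(cfg, tr, lx)
  list(tracts = tr$tracts, ses = tr$ses, is_desert = tr$is_desert,
       lexicons = lx, corpus = tws$corpus, truth = tws$truth)
}

#' Write a synthetic study to disk in the standard exchange formats
#'
#' Emits `tweets.jsonl`, `tracts.geojson`, `ses.csv`, `food_lexicon.csv`,
#' `sentiment_lexicon.csv`, and `truth.json` under `dir`, each readable by
#' the corresponding loader.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # tweets
  con <- file(file.path(dir, "tweets.jsonl"), "w")
  df <- as.data.frame(study$corpus)
  writeLines(vapply(seq_len(nrow(df)), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, na = "null",
                     digits = NA)
  }, character(1)), con)
  close(con)
  # tracts
  feats <- lapply(seq_len(nrow(study$tracts)), function(i) {
    ring <- study$tracts$rings[[i]][[1]]
    list(type = "Feature",
         properties = list(GEOID = study$tracts$tract_id[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "tracts.geojson"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(study$ses, file.path(dir, "ses.csv"), row.names = FALSE, na = "")
  write_food_lexicon(study$lexicons$food, file.path(dir, "food_lexicon.csv"))
  write.csv(data.frame(word = names(study$lexicons$sentiment),
                       polarity = ifelse(unclass(study$lexicons$sentiment) > 0,
                                         "positive", "negative")),
            file.path(dir, "sentiment_lexicon.csv"), row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
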