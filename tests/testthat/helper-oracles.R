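# Independent oracles and tiny fixture builders shared across tests.

# Build a food-lexicon CSV on disk from a keyword/category table (nutrient
# columns optional; absent ones are left empty).
write_lexicon_csv <- function(df, path = tempfile(fileext = ".csv")) {
  nf <- feature_names()$nutrient_fields
  for (col in nf) if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  utils::write.csv(df[c("keyword", "category", nf)], path,
                   row.names = FALSE, na = "")
  path
}

make_lexicon <- function(df) load_food_lexicon(write_lexicon_csv(df))

# A small deterministic lexicon with the nested-phrase patterns that make
# longest-first matching observable.
tiny_lexicon <- function() {
  make_lexicon(data.frame(
    keyword = c("burger king", "burger", "fries", "apple", "taco bell",
                "red velvet cake", "cake"),
    category = c("fastfood", "unhealthy", "unhealthy", "healthy",
                 "fastfood", "unhealthy", "unhealthy"),
    calories = c(NA, 254, 312, 52, NA, 367, 290),
    cholesterol = c(NA, 54, 0, 0, NA, 65, 58),
    potassium = c(NA, 198, 451, 107, NA, 105, 96),
    stringsAsFactors = FALSE
  ))
}

tiny_sentiment <- function() {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(word = c("love", "great", "hate", "awful"),
                              polarity = c("positive", "positive",
                                           "negative", "negative")),
                   path, row.names = FALSE)
  load_sentiment_lexicon(path)
}

# Corpus builder around the package's own constructor shape, via JSONL so
# the reader is exercised too when wanted.
make_corpus <- function(text, lat = 0.5, lon = 0.5, id = NULL) {
  n <- length(text)
  if (n == 0) {
    return(foodsignal:::new_tweet_corpus(data.frame(
      id = character(0), user_id = character(0), timestamp = character(0),
      text = character(0), lat = numeric(0), lon = numeric(0),
      stringsAsFactors = FALSE)))
  }
  df <- data.frame(
    id = id %||% sprintf("x%03d", seq_len(n)),
    user_id = "u1",
    timestamp = "2020-05-01T12:00:00Z",
    text = text,
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(n), function(i) {
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1)), path)
  read_tweets(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- matcher oracle: exhaustive candidate enumeration, longest-first ------
# Enumerates every (keyword, start) occurrence with plain loops, orders
# candidates by word count (desc), then start, with exact hits before
# plural-folded ones, and greedily accepts span-disjoint candidates.
oracle_match <- function(text, keywords, plural_fold = TRUE) {
  tokens <- tokenize_text(text)[[1]]
  n <- length(tokens)
  cand <- list()
  for (kw in keywords) {
    words <- strsplit(kw, " ", fixed = TRUE)[[1]]
    k <- length(words)
    if (k > n) next
    for (start in seq_len(n - k + 1)) {
      seg <- tokens[start:(start + k - 1)]
      exact <- all(seg == words)
      folded <- FALSE
      if (!exact && plural_fold && k == 1) {
        folded <- grepl("s$", seg) && nchar(seg) > 1 &&
          sub("s$", "", seg) == words
      }
      if (exact || folded) {
        cand[[length(cand) + 1]] <- list(kw = kw, start = start,
                                         end = start + k - 1, k = k,
                                         folded = folded)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(keyword = character(0), start = integer(0)))
  }
  ord <- order(-vapply(cand, `[[`, numeric(1), "k"),
               vapply(cand, `[[`, numeric(1), "start"),
               vapply(cand, `[[`, logical(1), "folded"))
  consumed <- logical(n)
  acc <- list()
  for (c0 in cand[ord]) {
    span <- c0$start:c0$end
    if (!any(consumed[span])) {
      consumed[span] <- TRUE
      acc[[length(acc) + 1]] <- c0
    }
  }
  acc <- acc[order(vapply(acc, `[[`, numeric(1), "start"))]
  data.frame(keyword = vapply(acc, `[[`, character(1), "kw"),
             start = vapply(acc, `[[`, numeric(1), "start"),
             stringsAsFactors = FALSE)
}

# --- AUC oracle: O(n^2) pair counting ------------------------------------
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# --- OLS oracle: direct normal-equations solve ---------------------------
oracle_ols <- function(y, fd, controls) {
  X <- cbind(1, fd, as.matrix(controls))
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(sigma2 * solve(XtX)))
  tval <- unname(beta[2] / se[2])
  list(beta_fd = unname(beta[2]), se = unname(se[2]),
       p_value = 2 * stats::pt(abs(tval), n - p, lower.tail = FALSE),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# --- point-in-polygon oracle: even-odd ray casting -----------------------
oracle_point_in_poly <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Small null-effect config used by calibration-style tests.
null_config <- function(n_tracts, seed) {
  synthetic_config(
    n_tracts = n_tracts, seed = seed,
    delta_pct_healthy_pos = 0, delta_pct_fastfood_pos = 0,
    delta_mean_unhealthy_mentions = 0,
    delta_cholesterol = 0, delta_potassium = 0
  )
}
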