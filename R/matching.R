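#' Tokenize short-text content for matching and sentiment scoring
#'
#' One canonical token stream feeds both keyword matching and sentiment
#' scoring: text is lowercased, URLs and @-mentions are removed, the '#' is
#' stripped from hashtags, and the remainder is split on non-alphanumeric
#' boundaries.
#'
#' @param text Character vector of raw texts.
#' @return A list of character token vectors, one per input text.
#' @export
#' @examples
#' tokenize_text("Craving @joe's Burger King!! #NoFilter http://t.co/x")
tokenize_text <- function(text) {
  text <- tolower(as.character(text))
  text <- gsub("https?://\\S+|www\\.\\S+", " ", text)
  text <- gsub("@\\w+", " ", text)
  text <- gsub("#", " ", text, fixed = TRUE)
  toks <- strsplit(text, "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

# Pre-extract per-word-count keyword tables from a lexicon for fast repeated
# matching over a corpus.
matcher_index <- function(lex) {
  stopifnot(inherits(lex, "food_lexicon"))
  e <- lex$entries
  ks <- as.integer(names(lex$word_count_index))
  lapply(seq_along(ks), function(j) {
    rows <- lex$word_count_index[[j]]
    list(k = ks[j], rows = rows, keywords = e$keyword[rows])
  })
}

# Core greedy longest-first matcher over a token vector. Returns entry row
# indices plus start positions, in text order.
match_tokens <- function(tokens, lex, index = matcher_index(lex),
                         plural_fold = TRUE) {
  n <- length(tokens)
  if (n == 0) return(list(row = integer(0), start = integer(0), end = integer(0)))
  consumed <- logical(n)
  out_row <- integer(0); out_start <- integer(0); out_end <- integer(0)
  for (level in index) {
    k <- level$k
    if (k > n) next
    if (k == 1) {
      hit <- match(tokens, level$keywords)
      if (plural_fold) {
        # a trailing-"s" token may match the singular keyword; an exact
        # lexicon hit takes precedence over the de-pluralized one
        fold <- is.na(hit) & grepl("s$", tokens) & nchar(tokens) > 1
        hit[fold] <- match(sub("s$", "", tokens[fold]), level$keywords)
      }
      starts <- which(!is.na(hit))
      ends <- starts
      rows <- level$rows[hit[starts]]
    } else {
      if (n - k + 1 < 1) next
      grams <- tokens
      for (j in seq_len(k - 1)) {
        grams <- paste(grams[-length(grams)], tokens[-seq_len(j)])
      }
      hit <- match(grams, level$keywords)
      starts <- which(!is.na(hit))
      ends <- starts + k - 1L
      rows <- level$rows[hit[starts]]
    }
    # left-to-right consumption within a word-count level
    for (j in seq_along(starts)) {
      span <- starts[j]:ends[j]
      if (!any(consumed[span])) {
        consumed[span] <- TRUE
        out_row <- c(out_row, rows[j])
        out_start <- c(out_start, starts[j])
        out_end <- c(out_end, ends[j])
      }
    }
  }
  ord <- order(out_start)
  list(row = out_row[ord], start = out_start[ord], end = out_end[ord])
}

#' Match food keywords in a text, longest phrases first
#'
#' Implements greedy longest-first multi-word matching: keywords with the
#' most words are sought first, each match consumes its tokens, and the
#' remaining tokens are searched for shorter keywords. This is what keeps a
#' mention of "Burger King" from also counting as a mention of "burger".
#' Within a word-count level occurrences are consumed left to right; no
#' token contributes to more than one match.
#'
#' Single-word keywords tolerate a simple plural (a trailing "s"), so
#' "burgers" matches the keyword "burger"; set `plural_fold = FALSE` for
#' exact-only matching.
#'
#' @param text A single character string.
#' @param lex A `food_lexicon`.
#' @param plural_fold Fold a trailing "s" when matching 1-word keywords.
#' @return A data.frame with one row per match: `keyword`, `category`,
#'   `start`, `end` (token positions), and the 17 nutrient columns.
#' @export
#' @examples
#' lex <- generate_lexicons(synthetic_config())$food
#' match_foods("Craving Burger King and a burger tonight", lex)
match_foods <- function(text, lex, plural_fold = TRUE) {
  stopifnot(length(text) == 1)
  tokens <- tokenize_text(text)[[1]]
  m <- match_tokens(tokens, lex, plural_fold = plural_fold)
  e <- lex$entries[m$row, , drop = FALSE]
  out <- data.frame(
    keyword = e$keyword %||% character(0),
    category = e$category %||% character(0),
    start = m$start, end = m$end,
    stringsAsFactors = FALSE
  )
  cbind(out, e[NUTRIENT_FIELDS])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score one tweet's food profile from its matches
#'
#' Tallies category mention counts and averages the per-100 g nutrient
#' profile over matched items. Averaging is available-case per nutrient: a
#' nutrient missing for some matched items (for example fast-food brand
#' names, which carry no nutrient row) is averaged over the items that have
#' it, and is missing in the result only when no matched item has it.
#' Calorie means are additionally computed within the healthy and unhealthy
#' categories.
#'
#' @param tweet_id Identifier copied into the profile.
#' @param matches A match data.frame from [match_foods()].
#' @return A one-row data.frame: `tweet_id`, `n_matches`, `n_healthy`,
#'   `n_unhealthy`, `n_fastfood`, 17 `mean_*` nutrient columns, and
#'   `mean_calories_healthy` / `mean_calories_unhealthy`.
#' @export
score_tweet <- function(tweet_id, matches) {
  nm <- nrow(matches)
  cat_counts <- vapply(FOOD_CATEGORIES,
                       function(cc) sum(matches$category == cc), integer(1))
  nut <- vapply(NUTRIENT_FIELDS, function(f) {
    v <- matches[[f]]
    if (nm == 0 || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  cal_by_cat <- vapply(c("healthy", "unhealthy"), function(cc) {
    v <- matches$calories[matches$category == cc]
    if (length(v) == 0 || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(
    tweet_id = tweet_id, n_matches = nm,
    n_healthy = cat_counts[["healthy"]],
    n_unhealthy = cat_counts[["unhealthy"]],
    n_fastfood = cat_counts[["fastfood"]],
    stringsAsFactors = FALSE
  )
  out[paste0("mean_", NUTRIENT_FIELDS)] <- as.list(nut)
  out$mean_calories_healthy <- cal_by_cat[["healthy"]]
  out$mean_calories_unhealthy <- cal_by_cat[["unhealthy"]]
  out
}

#' Profile every tweet in a food-filtered corpus
#'
#' Runs the longest-first matcher and per-tweet scoring over a corpus, and
#' (when a sentiment lexicon is supplied) appends the sentiment score,
#' label, and six category-by-polarity flags.
#'
#' @param corpus A `tweet_corpus` that has already passed
#'   [filter_food_related()]; a zero-match tweet is an internal-consistency
#'   error.
#' @param lex A `food_lexicon`.
#' @param sentiment_lex Optional `sentiment_lexicon`.
#' @param plural_fold Passed to the matcher.
#' @return A data.frame with one profile row per tweet (see
#'   [score_tweet()]), plus `sentiment_score`, `sentiment_label`, and the
#'   flag columns `healthy_pos` ... `fastfood_neg` when `sentiment_lex` is
#'   given.
#' @export
profile_corpus <- function(corpus, lex, sentiment_lex = NULL,
                           plural_fold = TRUE) {
  if (nrow(corpus) == 0) {
    return(empty_profile_frame(!is.null(sentiment_lex)))
  }
  idx <- matcher_index(lex)
  token_list <- tokenize_text(corpus$text)
  e <- lex$entries
  n <- nrow(corpus)
  match_rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- match_tokens(token_list[[i]], lex, index = idx,
                      plural_fold = plural_fold)
    if (length(m$row) == 0) {
      stop("tweet ", corpus$id[i], " has no food keyword match; ",
           "profile_corpus expects a food-filtered corpus")
    }
    match_rows[[i]] <- m$row
  }
  # vectorized equivalent of rbind(score_tweet(...) per tweet)
  item_tweet <- rep(seq_len(n), lengths(match_rows))
  item_row <- unlist(match_rows, use.names = FALSE)
  item_cat <- e$category[item_row]
  profiles <- data.frame(
    tweet_id = corpus$id,
    n_matches = as.integer(lengths(match_rows)),
    n_healthy = tabulate(item_tweet[item_cat == "healthy"], n),
    n_unhealthy = tabulate(item_tweet[item_cat == "unhealthy"], n),
    n_fastfood = tabulate(item_tweet[item_cat == "fastfood"], n),
    stringsAsFactors = FALSE
  )
  # available-case mean of `values` grouped by tweet index, over all n tweets
  avail_mean <- function(values, idx) {
    ok <- !is.na(values)
    s <- rep(0, n); k <- rep(0, n)
    if (any(ok)) {
      agg_s <- rowsum(values[ok], idx[ok])
      agg_k <- rowsum(rep(1, sum(ok)), idx[ok])
      at <- as.integer(rownames(agg_s))
      s[at] <- agg_s[, 1]; k[at] <- agg_k[, 1]
    }
    ifelse(k > 0, s / k, NA_real_)
  }
  for (nm in NUTRIENT_FIELDS) {
    profiles[[paste0("mean_", nm)]] <- avail_mean(e[[nm]][item_row], item_tweet)
  }
  for (cc in c("healthy", "unhealthy")) {
    sel <- item_cat == cc
    profiles[[paste0("mean_calories_", cc)]] <-
      avail_mean(e$calories[item_row[sel]], item_tweet[sel])
  }
  if (!is.null(sentiment_lex)) {
    score <- vapply(token_list, function(t) {
      sum(unclass(sentiment_lex)[match(t, names(sentiment_lex))], na.rm = TRUE)
    }, numeric(1))
    profiles$sentiment_score <- as.integer(score)
    profiles$sentiment_label <- sentiment_label(profiles$sentiment_score)
    flags <- flag_profiles(profiles, profiles$sentiment_label)
    profiles <- cbind(profiles, flags)
  }
  rownames(profiles) <- NULL
  profiles
}

empty_profile_frame <- function(with_sentiment) {
  out <- data.frame(tweet_id = character(0), n_matches = integer(0),
                    n_healthy = integer(0), n_unhealthy = integer(0),
                    n_fastfood = integer(0), stringsAsFactors = FALSE)
  out[paste0("mean_", NUTRIENT_FIELDS)] <- rep(list(numeric(0)), 17)
  out$mean_calories_healthy <- numeric(0)
  out$mean_calories_unhealthy <- numeric(0)
  if (with_sentiment) {
    out$sentiment_score <- integer(0)
    out$sentiment_label <- character(0)
    out[FLAG_COLUMNS] <- rep(list(logical(0)), 6)
  }
  out
}
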