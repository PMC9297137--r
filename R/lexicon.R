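#' Load and validate a food lexicon
#'
#' Reads a CSV of food keywords with their healthy/unhealthy/fast-food
#' category and per-100 g nutrient profile, normalizes keywords (lowercase,
#' internal whitespace collapsed), validates them, and builds the
#' word-count index used by the longest-first matcher.
#'
#' The expected columns are `keyword`, `category`, and the 17 nutrient
#' columns returned by `feature_names()$nutrient_fields`. Empty nutrient
#' cells are treated as missing; fast-food brand entries typically have a
#' fully missing nutrient profile.
#'
#' @param path Path to the lexicon CSV.
#' @return An object of class `food_lexicon`: a list with `entries` (a
#'   data.frame with `keyword`, `category`, `n_words`, and nutrient columns)
#'   and `word_count_index` (a list of entry row indices keyed by word
#'   count, in decreasing word-count order).
#' @export
load_food_lexicon <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("keyword", "category", NUTRIENT_FIELDS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("food lexicon is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  new_food_lexicon(
    keyword = as.character(df$keyword),
    category = as.character(df$category),
    nutrients = df[NUTRIENT_FIELDS]
  )
}

# Construct a validated food_lexicon from vectors (used by the loader and
# the synthetic generator).
new_food_lexicon <- function(keyword, category, nutrients) {
  keyword <- normalize_keyword(keyword)
  if (any(!nzchar(keyword))) stop("food lexicon contains an empty keyword")
  dup <- unique(keyword[duplicated(keyword)])
  if (length(dup) > 0) {
    stop("duplicate food lexicon keyword(s): ", paste(dup, collapse = ", "))
  }
  bad_cat <- unique(category[!category %in% FOOD_CATEGORIES])
  if (length(bad_cat) > 0) {
    stop("unknown food category value(s): ", paste(bad_cat, collapse = ", "),
         " (expected healthy, unhealthy or fastfood)")
  }
  nutrients <- as.data.frame(lapply(nutrients, function(x) {
    x <- suppressWarnings(as.numeric(x))
    x
  }))
  names(nutrients) <- NUTRIENT_FIELDS
  for (nm in NUTRIENT_FIELDS) {
    bad <- which(!is.na(nutrients[[nm]]) & nutrients[[nm]] < 0)
    if (length(bad) > 0) {
      stop("negative ", nm, " for keyword(s): ",
           paste(keyword[bad], collapse = ", "))
    }
  }
  entries <- data.frame(
    keyword = keyword,
    category = category,
    n_words = lengths(strsplit(keyword, " ", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  entries <- cbind(entries, nutrients)
  counts <- sort(unique(entries$n_words), decreasing = TRUE)
  idx <- lapply(counts, function(k) which(entries$n_words == k))
  names(idx) <- as.character(counts)
  structure(list(entries = entries, word_count_index = idx),
            class = "food_lexicon")
}

normalize_keyword <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Write a food lexicon back to CSV
#'
#' Inverse of [load_food_lexicon()]; round-tripping through disk yields an
#' identical lexicon.
#'
#' @param lex A `food_lexicon`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "food_lexicon"))
  out <- lex$entries[c("keyword", "category", NUTRIENT_FIELDS)]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a word-polarity sentiment lexicon
#'
#' Reads a CSV with columns `word` and `polarity` (the strings `positive`
#' or `negative`) and returns the +1/-1 scoring map used by
#' [sentiment_score()].
#'
#' @param path Path to the polarity CSV.
#' @return An object of class `sentiment_lexicon`: a named integer vector
#'   mapping lowercase words to +1 or -1.
#' @export
load_sentiment_lexicon <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("word", "polarity") %in% names(df))) {
    stop("sentiment lexicon must have columns word, polarity")
  }
  new_sentiment_lexicon(df$word, df$polarity)
}

new_sentiment_lexicon <- function(word, polarity) {
  word <- tolower(trimws(word))
  bad <- unique(polarity[!polarity %in% c("positive", "negative")])
  if (length(bad) > 0) {
    stop("polarity must be 'positive' or 'negative'; got: ",
         paste(bad, collapse = ", "))
  }
  value <- ifelse(polarity == "positive", 1L, -1L)
  # duplicates allowed only if they agree
  agg <- tapply(value, word, function(v) length(unique(v)))
  conflict <- names(agg)[agg > 1]
  if (length(conflict) > 0) {
    stop("conflicting polarity for word(s): ", paste(conflict, collapse = ", "))
  }
  keep <- !duplicated(word)
  structure(setNames(value[keep], word[keep]), class = "sentiment_lexicon")
}

#' Summarize a food lexicon
#'
#' Pure summary used for sanity-checking loaded lexicons: entry counts per
#' category and the fraction of entries missing each nutrient field.
#'
#' @param lex A `food_lexicon`.
#' @return A list with `n_entries`, `category_counts` (named integer vector
#'   over healthy/unhealthy/fastfood), and `nutrient_missingness` (named
#'   fraction in `[0, 1]` per nutrient field).
#' @export
validate_lexicon <- function(lex) {
  stopifnot(inherits(lex, "food_lexicon"))
  e <- lex$entries
  counts <- setNames(integer(length(FOOD_CATEGORIES)), FOOD_CATEGORIES)
  if (nrow(e) > 0) {
    tab <- table(factor(e$category, levels = FOOD_CATEGORIES))
    counts[names(tab)] <- as.integer(tab)
  }
  miss <- vapply(NUTRIENT_FIELDS, function(nm) {
    if (nrow(e) == 0) 0 else mean(is.na(e[[nm]]))
  }, numeric(1))
  list(n_entries = nrow(e), category_counts = counts,
       nutrient_missingness = miss)
}

#' @export
print.food_lexicon <- function(x, ...) {
  v <- validate_lexicon(x)
  cat("<food_lexicon>", v$n_entries, "entries (",
      paste(sprintf("%s: %d", names(v$category_counts), v$category_counts),
            collapse = ", "),
      ")\n")
  invisible(x)
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat("<sentiment_lexicon>", length(x), "words (",
      sum(x > 0), "positive,", sum(x < 0), "negative )\n")
  invisible(x)
}
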