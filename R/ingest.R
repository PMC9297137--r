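#' Read a tweet table from JSONL or CSV
#'
#' Expects one record per post with keys/columns `id`, `user_id`,
#' `timestamp`, `text`, `lat`, `lon`. Records missing `id` or `text` are
#' skipped (counted in the provenance note), not fatal; a file with zero
#' parseable records is an error.
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return A `tweet_corpus`: a data.frame (`id`, `user_id`, `timestamp`,
#'   `text`, `lat`, `lon`) with a `provenance` attribute recording the
#'   source path, skip count, and filter history.
#' @export
read_tweets <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("tweet file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    ok <- !vapply(recs, is.null, logical(1))
    recs <- recs[ok]
    n_bad_parse <- sum(!ok)
    get <- function(r, k) {
      v <- r[[k]]
      if (is.null(v) || length(v) == 0) NA else v
    }
    df <- data.frame(
      id = vapply(recs, function(r) as.character(get(r, "id")), character(1)),
      user_id = vapply(recs, function(r) as.character(get(r, "user_id")), character(1)),
      timestamp = vapply(recs, function(r) as.character(get(r, "timestamp")), character(1)),
      text = vapply(recs, function(r) as.character(get(r, "text")), character(1)),
      lat = vapply(recs, function(r) suppressWarnings(as.numeric(get(r, "lat"))), numeric(1)),
      lon = vapply(recs, function(r) suppressWarnings(as.numeric(get(r, "lon"))), numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(id = "character", user_id = "character",
                                  timestamp = "character", text = "character"))
    n_bad_parse <- 0L
    for (col in c("id", "user_id", "timestamp", "text", "lat", "lon")) {
      if (!col %in% names(df)) df[[col]] <- NA
    }
    df <- df[c("id", "user_id", "timestamp", "text", "lat", "lon")]
    df$lat <- suppressWarnings(as.numeric(df$lat))
    df$lon <- suppressWarnings(as.numeric(df$lon))
  }
  usable <- !is.na(df$id) & !is.na(df$text)
  n_skipped <- sum(!usable) + n_bad_parse
  df <- df[usable, , drop = FALSE]
  if (nrow(df) == 0) stop("no parseable tweet records in ", path)
  if (anyDuplicated(df$id)) {
    stop("duplicate tweet id(s) in ", path, ": ",
         paste(head(unique(df$id[duplicated(df$id)]), 5), collapse = ", "))
  }
  rownames(df) <- NULL
  new_tweet_corpus(df, source = path, skipped = n_skipped)
}

new_tweet_corpus <- function(df, source = NA_character_, skipped = 0L,
                             filters = character(0)) {
  structure(df,
            provenance = list(source = source, skipped = skipped,
                              filters = filters),
            class = c("tweet_corpus", "data.frame"))
}

corpus_keep <- function(corpus, keep, filter_name) {
  prov <- attr(corpus, "provenance")
  df <- as.data.frame(corpus)[keep, , drop = FALSE]
  rownames(df) <- NULL
  new_tweet_corpus(df, source = prov$source, skipped = prov$skipped,
                   filters = c(prov$filters, filter_name))
}

#' @export
print.tweet_corpus <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<tweet_corpus>", nrow(x), "tweets")
  if (length(prov$filters)) cat(" | filters:", paste(prov$filters, collapse = " > "))
  cat("\n")
  invisible(x)
}

#' Keep only tweets with usable GPS coordinates
#'
#' Tweets survive only when both latitude and longitude are present and in
#' range (`[-90, 90]` and `[-180, 180]`); order is preserved.
#'
#' @param corpus A `tweet_corpus`.
#' @return The filtered `tweet_corpus`.
#' @export
filter_geolocated <- function(corpus) {
  keep <- !is.na(corpus$lat) & !is.na(corpus$lon) &
    corpus$lat >= -90 & corpus$lat <= 90 &
    corpus$lon >= -180 & corpus$lon <= 180
  corpus_keep(corpus, keep, "geolocated")
}

#' Remove promotional tweets by hashtag/keyword blocklist
#'
#' A tweet is removed when its lowercased text contains any blocklist entry
#' as a whole whitespace-delimited token, so `#ad` removes "check this #ad"
#' but not "#AdVice", and "job" in running text is not hit by `#jobs`.
#'
#' @param corpus A `tweet_corpus`.
#' @param blocklist Character vector of lowercase tokens; the default
#'   covers the job-posting and advertising tags.
#' @return The filtered `tweet_corpus`.
#' @export
filter_promotional <- function(corpus,
                               blocklist = c("#jobs", "#hiring", "#ad", "#job")) {
  stopifnot(length(blocklist) > 0)
  if (nrow(corpus) == 0) return(corpus_keep(corpus, logical(0), "promotional"))
  toks <- strsplit(tolower(corpus$text), "[[:space:]]+")
  hit <- vapply(toks, function(t) any(t %in% blocklist), logical(1))
  corpus_keep(corpus, !hit, "promotional")
}

#' Keep only tweets that mention at least one food keyword
#'
#' A tweet survives if and only if the longest-first matcher finds at least
#' one match in its text.
#'
#' @param corpus A `tweet_corpus`.
#' @param lex A `food_lexicon`.
#' @param plural_fold Passed to the matcher.
#' @return The filtered `tweet_corpus`.
#' @export
filter_food_related <- function(corpus, lex, plural_fold = TRUE) {
  if (nrow(corpus) == 0) return(corpus_keep(corpus, logical(0), "food_related"))
  idx <- matcher_index(lex)
  token_list <- tokenize_text(corpus$text)
  keep <- vapply(token_list, function(t) {
    length(match_tokens(t, lex, index = idx, plural_fold = plural_fold)$row) > 0
  }, logical(1))
  corpus_keep(corpus, keep, "food_related")
}
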