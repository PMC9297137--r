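FLAG_COLUMNS <- c("healthy_pos", "healthy_neg", "unhealthy_pos",
                  "unhealthy_neg", "fastfood_pos", "fastfood_neg")

#' Lexicon sentiment score of a text
#'
#' Sums word polarities (+1 positive, -1 negative) over the text's tokens;
#' words absent from the polarity lexicon contribute 0. Repeated polarity
#' words count once per occurrence.
#'
#' @param text A single character string.
#' @param lex A `sentiment_lexicon`.
#' @return An integer score.
#' @export
#' @examples
#' lex <- generate_lexicons(synthetic_config())$sentiment
#' sentiment_score("I love love this awful pizza", lex)
sentiment_score <- function(text, lex) {
  stopifnot(length(text) == 1, inherits(lex, "sentiment_lexicon"))
  tokens <- tokenize_text(text)[[1]]
  as.integer(sum(unclass(lex)[match(tokens, names(lex))], na.rm = TRUE))
}

#' Map a sentiment score to a label
#'
#' Positive scores are `positive`, negative scores `negative`, and a score
#' of exactly 0 is `neutral`.
#'
#' @param score Integer vector of sentiment scores.
#' @return Character vector of labels.
#' @export
sentiment_label <- function(score) {
  ifelse(score > 0, "positive", ifelse(score < 0, "negative", "neutral"))
}

#' Derive the six category-by-polarity flags for one tweet
#'
#' For each food category mentioned at least once in the tweet's profile,
#' the flag matching the tweet's sentiment polarity is set; a neutral tweet
#' sets no flags, and at most one of the positive/negative flags per
#' category can be set.
#'
#' @param profile A one-row profile data.frame from [score_tweet()] (needs
#'   `n_healthy`, `n_unhealthy`, `n_fastfood`).
#' @param label `"positive"`, `"negative"`, or `"neutral"`.
#' @return A named logical vector over `healthy_pos` ... `fastfood_neg`.
#' @export
flag_tweet <- function(profile, label) {
  stopifnot(label %in% c("positive", "negative", "neutral"))
  counts <- c(healthy = profile$n_healthy[1],
              unhealthy = profile$n_unhealthy[1],
              fastfood = profile$n_fastfood[1])
  flags <- setNames(logical(6), FLAG_COLUMNS)
  if (label != "neutral") {
    suffix <- if (label == "positive") "_pos" else "_neg"
    hit <- names(counts)[counts >= 1]
    if (length(hit) > 0) flags[paste0(hit, suffix)] <- TRUE
  }
  flags
}

# Vectorized flag derivation over a profile frame.
flag_profiles <- function(profiles, labels) {
  out <- as.data.frame(setNames(rep(list(logical(nrow(profiles))), 6),
                                FLAG_COLUMNS))
  pos <- labels == "positive"
  neg <- labels == "negative"
  for (cc in FOOD_CATEGORIES) {
    has <- profiles[[paste0("n_", cc)]] >= 1
    out[[paste0(cc, "_pos")]] <- has & pos
    out[[paste0(cc, "_neg")]] <- has & neg
  }
  out
}
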