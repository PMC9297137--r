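#' Run the full tract-level analysis pipeline
#'
#' Chains every stage on in-memory study inputs: ingest filtering
#' (geolocation, promotional blocklist, food-keyword requirement),
#' per-tweet matching/scoring with sentiment, tract mapping, feature
#' aggregation with SES merge and USDA labeling, the adjusted association
#' screen, and (optionally) the five-model classification benchmark.
#'
#' @param corpus A `tweet_corpus` (e.g. from [read_tweets()] or
#'   [generate_study()]).
#' @param tracts A `tract_set`.
#' @param ses SES/labeling data.frame.
#' @param food_lex A `food_lexicon`.
#' @param sentiment_lex A `sentiment_lexicon`.
#' @param seed Integer seed for the benchmark split and learners.
#' @param mode Tract assignment mode (`"bbox"` or `"polygon"`).
#' @param alpha Screen significance level.
#' @param benchmark Run the classification benchmark (the slow stage)?
#' @param grids Hyperparameter grids for the benchmark.
#' @param blocklist Promotional token blocklist.
#' @return A list with `counts` (corpus size after each filter), `table`
#'   (the analysis table), `screen` (an `association_screen`), and
#'   `benchmark` (20-row results, or `NULL`).
#' @export
run_pipeline <- function(corpus, tracts, ses, food_lex, sentiment_lex,
                         seed = 1, mode = "bbox", alpha = 0.05,
                         benchmark = TRUE, grids = default_hyper_grid(),
                         blocklist = c("#jobs", "#hiring", "#ad", "#job")) {
  counts <- c(raw = nrow(corpus))
  corpus <- filter_geolocated(corpus)
  counts["geolocated"] <- nrow(corpus)
  corpus <- filter_promotional(corpus, blocklist)
  counts["non_promotional"] <- nrow(corpus)
  corpus <- filter_food_related(corpus, food_lex)
  counts["food_related"] <- nrow(corpus)
  profiles <- profile_corpus(corpus, food_lex, sentiment_lex)
  mapping <- map_corpus(corpus, tracts, mode = mode)
  table <- build_analysis_table(profiles, mapping, ses)
  screen <- run_association_screen(table, alpha = alpha)
  bench <- if (benchmark) {
    run_benchmark(table, seed = seed, screen = screen, grids = grids)
  } else {
    NULL
  }
  list(counts = counts, table = table, screen = screen, benchmark = bench)
}

#' City share arithmetic for a collection summary
#'
#' Given per-city tweet and user counts, computes each city's percentage
#' share of the collection (the shape of a collection-summary table). A
#' copy of the 25-city counts from the 2020 collection ships in
#' `inst/extdata/city_tweet_counts.csv`.
#'
#' @param counts Data.frame with columns `city`, `n_tweets`, `n_users`.
#' @return The input with `pct_tweets` and `pct_users` columns (rounded to
#'   2 decimals) plus totals in attributes `total_tweets` / `total_users`.
#' @export
city_share_report <- function(counts) {
  stopifnot(all(c("city", "n_tweets", "n_users") %in% names(counts)))
  out <- counts
  out$pct_tweets <- round(100 * counts$n_tweets / sum(counts$n_tweets), 2)
  out$pct_users <- round(100 * counts$n_users / sum(counts$n_users), 2)
  structure(out, total_tweets = sum(counts$n_tweets),
            total_users = sum(counts$n_users))
}

#' Share of manually audited tweets confirmed food-related
#'
#' Arithmetic check for a keyword-filter audit: the percentage of audited
#' tweets whose food-keyword match reflected genuine food content. A tally
#' of the published 1000-tweet audit ships in
#' `inst/extdata/manual_annotation_tally.csv`.
#'
#' @param tally Data.frame with columns `label` (containing
#'   `food_related` / `not_food_related`) and `n`.
#' @return Percentage of audited tweets labeled food-related.
#' @export
annotation_food_related_pct <- function(tally) {
  stopifnot(all(c("label", "n") %in% names(tally)))
  100 * tally$n[tally$label == "food_related"] / sum(tally$n)
}
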