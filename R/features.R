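#' Aggregate per-tweet profiles to census-tract ingestion features
#'
#' Produces one record per tract with at least one mapped tweet, holding
#' the 28 tract-level ingestion features: six sentiment percentages (the
#' share of all the tract's food-related tweets carrying each
#' category-by-polarity flag; neutral tweets stay in the denominator),
#' three mean mention counts, 17 mean per-item nutrient values, and the
#' healthy/unhealthy calorie means. Nutrient aggregation is available-case:
#' the tract mean averages the per-tweet means of the tweets that have the
#' nutrient, and is missing only when no tweet contributes.
#'
#' @param profiles A profile frame from [profile_corpus()] including
#'   sentiment flags.
#' @param mapping A tweet-to-tract data.frame from [map_corpus()]; profile
#'   rows absent from the mapping are dropped as unmapped.
#' @param tract_ids Optional vector of known tract ids; a mapped tract
#'   outside this set is an error.
#' @return A data.frame with `tract_id`, `n_tweets`, and the 28 feature
#'   columns.
#' @export
aggregate_tract_features <- function(profiles, mapping, tract_ids = NULL) {
  stopifnot(all(FLAG_COLUMNS %in% names(profiles)))
  m <- match(profiles$tweet_id, mapping$tweet_id)
  keep <- !is.na(m)
  profiles <- profiles[keep, , drop = FALSE]
  tract <- mapping$tract_id[m[keep]]
  if (!is.null(tract_ids)) {
    unknown <- setdiff(unique(tract), tract_ids)
    if (length(unknown) > 0) {
      stop("tweet(s) mapped to unknown tract(s): ",
           paste(head(unknown, 5), collapse = ", "))
    }
  }
  if (nrow(profiles) == 0) {
    stop("no mapped profiles to aggregate")
  }
  f <- factor(tract)
  n_tweets <- as.integer(table(f))
  out <- data.frame(tract_id = levels(f), n_tweets = n_tweets,
                    stringsAsFactors = FALSE)
  # sentiment percentages over all of the tract's food-related tweets
  for (j in seq_along(FLAG_COLUMNS)) {
    num <- rowsum(as.numeric(profiles[[FLAG_COLUMNS[j]]]), f)
    out[[SENTIMENT_FEATURES[j]]] <- 100 * as.numeric(num) / n_tweets
  }
  mention_src <- c("n_healthy", "n_unhealthy", "n_fastfood")
  for (j in seq_along(MENTION_FEATURES)) {
    tot <- rowsum(as.numeric(profiles[[mention_src[j]]]), f)
    out[[MENTION_FEATURES[j]]] <- as.numeric(tot) / n_tweets
  }
  # available-case tract means of per-tweet nutrient means
  for (col in NUTRIENT_FEATURES) {
    v <- profiles[[col]]
    ok <- !is.na(v)
    s <- as.numeric(rowsum(ifelse(ok, v, 0), f))
    k <- as.numeric(rowsum(as.numeric(ok), f))
    out[[col]] <- ifelse(k > 0, s / k, NA_real_)
  }
  out
}

#' Merge tract ingestion features with SES covariates
#'
#' Inner join on `tract_id`; feature tracts lacking an SES row are dropped
#' (the count is recorded in attribute `n_dropped`). Duplicate tract ids on
#' either side are an error.
#'
#' @param features Output of [aggregate_tract_features()].
#' @param ses SES/demographics data.frame with `tract_id`, the 12
#'   covariates, and the USDA labeling fields.
#' @return The merged analysis table.
#' @export
merge_ses <- function(features, ses) {
  if (anyDuplicated(features$tract_id)) stop("duplicate tract_id in features")
  if (anyDuplicated(ses$tract_id)) stop("duplicate tract_id in SES table")
  m <- match(features$tract_id, ses$tract_id)
  keep <- !is.na(m)
  out <- cbind(features[keep, , drop = FALSE],
               ses[m[keep], setdiff(names(ses), "tract_id"), drop = FALSE])
  rownames(out) <- NULL
  structure(out, n_dropped = sum(!keep))
}

#' Label a tract as a food desert by USDA criteria
#'
#' A tract is a food desert when it is both low-income and low-access.
#' Low-income: at least 20% of residents below the federal poverty level,
#' or median family income at most 80% of the state median, or (when the
#' tract is in a metropolitan area, i.e. a metro median is supplied) at
#' most 80% of the metro median. Low-access: at least 500 individuals or at
#' least 33% of residents far from a supermarket. All boundaries are
#' inclusive.
#'
#' @param ses A data.frame with one row per tract carrying
#'   `pct_below_poverty`, `median_family_income`,
#'   `state_median_family_income`, `metro_median_family_income` (may be
#'   `NA`), `n_low_access`, and `pct_low_access`.
#' @return A data.frame with `tract_id` (if present in `ses`),
#'   `low_income`, `low_access`, `is_food_desert`, and logical columns for
#'   the individual criteria (`poverty20`, `income80_state`,
#'   `income80_metro`, `access500`, `access33pct`).
#' @export
label_food_desert <- function(ses) {
  need <- c("pct_below_poverty", "median_family_income",
            "state_median_family_income", "n_low_access", "pct_low_access")
  missing_cols <- setdiff(need, names(ses))
  if (length(missing_cols) > 0) {
    stop("SES table is missing labeling fields: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(ses$n_low_access < 0, na.rm = TRUE)) {
    stop("negative n_low_access count")
  }
  metro <- if ("metro_median_family_income" %in% names(ses)) {
    ses$metro_median_family_income
  } else {
    rep(NA_real_, nrow(ses))
  }
  poverty20 <- ses$pct_below_poverty >= 20
  income80_state <- ses$median_family_income <=
    0.8 * ses$state_median_family_income
  income80_metro <- !is.na(metro) & ses$median_family_income <= 0.8 * metro
  access500 <- ses$n_low_access >= 500
  access33pct <- ses$pct_low_access >= 33
  low_income <- poverty20 | income80_state | income80_metro
  low_access <- access500 | access33pct
  out <- data.frame(
    low_income = low_income, low_access = low_access,
    is_food_desert = low_income & low_access,
    poverty20 = poverty20, income80_state = income80_state,
    income80_metro = income80_metro, access500 = access500,
    access33pct = access33pct
  )
  if ("tract_id" %in% names(ses)) {
    out <- cbind(tract_id = ses$tract_id, out)
  }
  out
}

#' Build the tract-level analysis table
#'
#' Convenience wrapper: aggregates profiles, merges SES covariates, and
#' appends the food-desert label columns. This table is the contract
#' between the upstream text pipeline and the statistical modules.
#'
#' @param profiles Profile frame with sentiment flags.
#' @param mapping Tweet-to-tract mapping.
#' @param ses SES table (12 covariates plus labeling fields).
#' @return The analysis table: `tract_id`, `n_tweets`, 28 ingestion
#'   features, SES columns, and label columns.
#' @export
build_analysis_table <- function(profiles, mapping, ses) {
  feats <- aggregate_tract_features(profiles, mapping,
                                    tract_ids = ses$tract_id)
  tab <- merge_ses(feats, ses)
  lab <- label_food_desert(tab)
  cbind(tab, lab[setdiff(names(lab), "tract_id")])
}
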