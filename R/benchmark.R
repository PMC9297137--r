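#' Feature columns for each benchmark model specification
#'
#' Model 1 is the SES-only baseline; model 2 adds the nutrient features;
#' model 3 adds the six sentiment-percentage features; model 4 adds both;
#' model 5 adds whichever ingestion features the association screen found
#' significant.
#'
#' @param model_id Integer in 1..5.
#' @param screen An `association_screen` (required for model 5).
#' @return Character vector of analysis-table column names.
#' @export
model_feature_set <- function(model_id, screen = NULL) {
  stopifnot(model_id %in% 1:5)
  extra <- switch(model_id,
    character(0),
    NUTRIENT_FEATURES,
    SENTIMENT_FEATURES,
    c(NUTRIENT_FEATURES, SENTIMENT_FEATURES),
    {
      if (is.null(screen)) stop("model 5 requires an association screen result")
      screen$significant
    }
  )
  c(SES_FIELDS, extra)
}

# Train-median imputation; the medians come from training rows only.
impute_median <- function(train, test) {
  med <- vapply(train, function(v) {
    m <- stats::median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  fill <- function(df) {
    for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- med[j]
    df
  }
  list(train = fill(train), test = fill(test), medians = med)
}

#' Benchmark the five feature-set models across four classifiers
#'
#' The complete evaluation: for each of the five model specifications the
#' feature columns are selected, missing values imputed with training-set
#' medians, features min-max scaled on the training rows, and each of the
#' four methods (adaptive boosting, gradient boosting, logistic
#' regression, stacked ensemble) trained with CV hyperparameter selection
#' and scored on the held-out 30% test rows by AUC. Cross-validation is
#' used for hyperparameter selection only; the reported AUC is always on
#' the untouched test split.
#'
#' @param table Analysis table with `is_food_desert` labels.
#' @param seed Integer seed controlling the split, folds, and learners.
#' @param screen An `association_screen` for model 5; computed from
#'   `table` with default `alpha` when not supplied.
#' @param train_frac,n_folds Split configuration (defaults 0.70 and 5).
#' @param grids Hyperparameter grids, as [default_hyper_grid()].
#' @param methods Subset of methods to run (default all four).
#' @param models Subset of model ids to run (default 1..5).
#' @return A data.frame with one row per method-by-model cell (20 rows in
#'   the full run): `method`, `model_id`, `auc`, `delta_vs_baseline`, and
#'   `seed`.
#' @export
run_benchmark <- function(table, seed = 1, screen = NULL, train_frac = 0.7,
                          n_folds = 5, grids = default_hyper_grid(),
                          methods = CLASSIFIER_METHODS, models = 1:5) {
  methods <- match.arg(methods, CLASSIFIER_METHODS, several.ok = TRUE)
  labels <- as.integer(as.logical(table$is_food_desert))
  if (min(table(labels)) < 10) {
    stop("need at least 10 rows per class to benchmark")
  }
  if (is.null(screen) && 5 %in% models) {
    screen <- run_association_screen(table)
  }
  sp <- split_data(labels, train_frac = train_frac, n_folds = n_folds,
                   seed = seed)
  y_tr <- labels[sp$train_idx]
  y_te <- labels[sp$test_idx]
  rows <- list()
  for (mid in models) {
    cols <- model_feature_set(mid, screen)
    x_tr <- table[sp$train_idx, cols, drop = FALSE]
    x_te <- table[sp$test_idx, cols, drop = FALSE]
    imp <- impute_median(x_tr, x_te)
    sc <- minmax_fit_apply(imp$train, imp$test)
    for (m in methods) {
      fit <- if (m == "ensemble") {
        train_ensemble(sc$train, y_tr, sp$folds, grids = grids, seed = seed)
      } else {
        train_learner(m, sc$train, y_tr, sp$folds, grid = grids[[m]],
                      seed = seed)
      }
      scores <- predict(fit, sc$test)
      rows[[length(rows) + 1]] <- data.frame(
        method = m, model_id = mid, auc = compute_auc(scores, y_te),
        seed = seed, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$method, CLASSIFIER_METHODS), out$model_id), ]
  rownames(out) <- NULL
  base <- out$auc[match(paste(out$method, min(models)),
                        paste(out$method, out$model_id))]
  out$delta_vs_baseline <- out$auc - base
  out[c("method", "model_id", "auc", "delta_vs_baseline", "seed")]
}
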