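#' Min-max normalization fit on training data only
#'
#' Rescales each feature by its training-set minimum and maximum,
#' `(x - min) / (max - min)`. A constant training column maps to all zeros.
#' Test values are transformed with the training parameters and are not
#' clipped, so they may fall outside `[0, 1]` — estimating the range from
#' anything but the training rows would leak test information.
#'
#' @param train Training feature data.frame/matrix (non-empty).
#' @param test Optional test feature table with the same columns.
#' @return A list with `train`, `test` (scaled data.frames; `test` is
#'   `NULL` when absent), and `ranges` (data.frame `feature`, `min`, `max`).
#' @export
minmax_fit_apply <- function(train, test = NULL) {
  train <- as.data.frame(train)
  stopifnot(nrow(train) > 0)
  if (!is.null(test)) {
    test <- as.data.frame(test)
    missing_cols <- setdiff(names(train), names(test))
    if (length(missing_cols) > 0) {
      stop("test table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    test <- test[names(train)]
  }
  mins <- vapply(train, min, numeric(1))
  maxs <- vapply(train, max, numeric(1))
  scale_one <- function(df) {
    out <- df
    for (j in seq_along(df)) {
      rng <- maxs[j] - mins[j]
      out[[j]] <- if (rng == 0) rep(0, nrow(df)) else (df[[j]] - mins[j]) / rng
    }
    out
  }
  list(train = scale_one(train),
       test = if (is.null(test)) NULL else scale_one(test),
       ranges = data.frame(feature = names(train), min = unname(mins),
                           max = unname(maxs), stringsAsFactors = FALSE))
}

#' Stratified 70:30 split with stratified CV folds
#'
#' Splits rows into training and test sets stratified by the binary label,
#' then partitions the training rows into stratified cross-validation
#' folds. Everything is determined by the seed.
#'
#' @param labels Binary (0/1 or logical) label vector.
#' @param train_frac Training fraction (default 0.70).
#' @param n_folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @return A list with `train_idx`, `test_idx` (row indices) and `folds`
#'   (integer fold id per training row, parallel to `train_idx`).
#' @export
split_data <- function(labels, train_frac = 0.7, n_folds = 5, seed = 1) {
  labels <- as.integer(as.logical(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("both classes must be present to split")
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in classes) {
    rows <- which(labels == cl)
    n_tr <- round(train_frac * length(rows))
    train_idx <- c(train_idx, sample(rows, n_tr))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(labels), train_idx)
  folds <- integer(length(train_idx))
  for (cl in classes) {
    pos <- which(labels[train_idx] == cl)
    folds[sample(pos)] <- rep_len(seq_len(n_folds), length(pos))
  }
  list(train_idx = train_idx, test_idx = test_idx, folds = folds)
}

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney form: the probability that a random
#' positive outranks a random negative, with half credit for tied scores.
#' Equivalent to explicit pair counting but O(n log n) via ranks.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Binary (0/1 or logical) labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
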