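#' Covariate-adjusted linear association of one ingestion feature
#'
#' Fits ordinary least squares for one tract-level ingestion feature as the
#' outcome, with the food-desert indicator as the treatment term and the 12
#' SES covariates as controls:
#' `y = b0 + b_FD * fd + b_1 x_1 + ... + b_12 x_12 + error`.
#' Rows with any missing value are dropped listwise. The reported p-value
#' is the two-sided t-test on the food-desert coefficient.
#'
#' @param y Numeric outcome vector (one ingestion feature).
#' @param fd Binary (0/1 or logical) food-desert indicator.
#' @param controls Data.frame or matrix of the SES covariates.
#' @param feature Optional feature name carried into the result.
#' @return A one-row data.frame: `feature`, `beta`, `se`, `p_value`,
#'   `r_squared`, `n` (rows used), `n_dropped`.
#' @export
fit_adjusted_model <- function(y, fd, controls, feature = NA_character_) {
  fd <- as.numeric(fd)
  controls <- as.matrix(controls)
  stopifnot(length(y) == length(fd), nrow(controls) == length(y))
  ok <- !is.na(y) & !is.na(fd) & stats::complete.cases(controls)
  n_dropped <- sum(!ok)
  y <- y[ok]; fd <- fd[ok]; controls <- controls[ok, , drop = FALSE]
  n <- length(y)
  p <- 2L + ncol(controls)
  if (n < p + 1) stop("too few complete rows (", n, ") for ", p, " parameters")
  if (stats::var(y) == 0) {
    # all-constant outcome: no association by convention
    return(data.frame(feature = feature, beta = 0, se = NA_real_,
                      p_value = 1, r_squared = 0, n = n,
                      n_dropped = n_dropped, stringsAsFactors = FALSE))
  }
  X <- cbind(`(Intercept)` = 1, fd = fd, controls)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
  se_fd <- sqrt(sigma2 * XtX_inv[2, 2])
  tval <- beta[["fd"]] / se_fd
  data.frame(
    feature = feature,
    beta = beta[["fd"]],
    se = se_fd,
    p_value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
    r_squared = 1 - rss / sum((y - mean(y))^2),
    n = n, n_dropped = n_dropped,
    stringsAsFactors = FALSE
  )
}

#' Screen all 28 ingestion features against food-desert status
#'
#' Runs [fit_adjusted_model()] once per ingestion feature, in the canonical
#' feature order, and collects the features whose food-desert coefficient
#' is significant at `alpha`. No multiple-testing correction is applied;
#' raw p-values are reported.
#'
#' @param table Analysis table from [build_analysis_table()] (needs the 28
#'   feature columns, `is_food_desert`, and the 12 SES columns).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `association_screen`: a list with `results`
#'   (28-row data.frame), `significant` (character vector of feature
#'   names), and `alpha`.
#' @export
run_association_screen <- function(table, alpha = 0.05) {
  missing_cols <- setdiff(c(TWITTER_FEATURES, "is_food_desert", SES_FIELDS),
                          names(table))
  if (length(missing_cols) > 0) {
    stop("analysis table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  controls <- table[SES_FIELDS]
  fd <- as.numeric(table$is_food_desert)
  results <- do.call(rbind, lapply(TWITTER_FEATURES, function(f) {
    fit_adjusted_model(table[[f]], fd, controls, feature = f)
  }))
  rownames(results) <- NULL
  structure(
    list(results = results,
         significant = results$feature[results$p_value < alpha],
         alpha = alpha),
    class = "association_screen"
  )
}

#' @export
print.association_screen <- function(x, ...) {
  cat("<association_screen>", nrow(x$results), "features;",
      length(x$significant), "significant at alpha =", x$alpha, "\n")
  if (length(x$significant)) {
    cat("  ", paste(x$significant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the association screen report to CSV
#'
#' One row per ingestion feature with the food-desert coefficient, raw
#' p-value, standard error, and R-squared, in the canonical feature order.
#'
#' @param screen An `association_screen` (or its `results` data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(screen, path) {
  results <- if (inherits(screen, "association_screen")) screen$results else screen
  out <- results[c("feature", "beta", "p_value", "se", "r_squared")]
  write.csv(format(out, digits = 15, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
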