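CLASSIFIER_METHODS <- c("adaptive_boosting", "gradient_boosting",
                        "logistic_regression", "ensemble")

#' Default hyperparameter grids for the benchmark learners
#'
#' Small fixed grids searched by mean cross-validated AUC: boosting rounds
#' for the stump-based adaptive booster, tree depth and rounds for the
#' gradient booster. Plain maximum-likelihood logistic regression has no
#' tuned hyperparameter.
#'
#' @return Named list of data.frame grids.
#' @export
default_hyper_grid <- function() {
  list(
    adaptive_boosting = data.frame(n_rounds = c(40, 80)),
    gradient_boosting = expand.grid(max_depth = c(2, 3), nrounds = c(60, 120),
                                    eta = 0.1),
    logistic_regression = data.frame(dummy = 0)
  )
}

# ---- adaptive boosting: exponentially reweighted decision stumps --------

fit_adaboost <- function(x, y, n_rounds) {
  n <- nrow(x)
  yf <- ifelse(y == 1, 1, -1)
  dat <- cbind(x, .y = factor(yf, levels = c(-1, 1)))
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    pred <- as.numeric(as.character(predict(fit, dat, type = "class")))
    err <- sum(w[pred != yf])
    if (err >= 0.5) break
    err <- max(err, 1e-12)
    alpha <- 0.5 * log((1 - err) / err)
    used <- used + 1L
    stumps[[used]] <- fit
    alphas[used] <- alpha
    w <- w * exp(-alpha * yf * pred)
    w <- w / sum(w)
    # a stump with no split predicts a constant; nothing changes after it
    if (is.null(fit$splits) || nrow(fit$splits) == 0) break
    if (err <= 1e-10) break
  }
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)])
}

predict_adaboost <- function(model, newx) {
  if (length(model$stumps) == 0) return(rep(0.5, nrow(newx)))
  F <- rep(0, nrow(newx))
  for (t in seq_along(model$stumps)) {
    h <- as.numeric(as.character(predict(model$stumps[[t]], newx,
                                         type = "class")))
    F <- F + model$alphas[t] * h
  }
  stats::plogis(2 * F)
}

# ---- single-method fit/predict dispatch ---------------------------------

fit_method <- function(method, x, y, params, seed = 1) {
  if (method == "adaptive_boosting") {
    fit_adaboost(x, y, params$n_rounds)
  } else if (method == "gradient_boosting") {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth, nthread = 1,
                    verbosity = 0),
      data = dtrain, nrounds = params$nrounds
    )
  } else if (method == "logistic_regression") {
    dat <- cbind(x, .y = y)
    suppressWarnings(stats::glm(.y ~ ., data = dat,
                                family = stats::binomial()))
  } else {
    stop("unknown method: ", method)
  }
}

predict_method <- function(method, model, newx) {
  if (method == "adaptive_boosting") {
    predict_adaboost(model, newx)
  } else if (method == "gradient_boosting") {
    predict(model, xgboost::xgb.DMatrix(as.matrix(newx)))
  } else {
    suppressWarnings(unname(predict(model, newdata = newx,
                                    type = "response")))
  }
}

# Mean cross-validated AUC for one hyperparameter setting. A degenerate
# (single-class) fold is refolded with a shifted seed.
cv_auc <- function(method, x, y, folds, params, seed) {
  n_folds <- max(folds)
  tries <- 0
  repeat {
    degenerate <- any(vapply(unique(folds), function(k) {
      length(unique(y[folds == k])) < 2
    }, logical(1)))
    if (!degenerate) break
    tries <- tries + 1
    if (tries > 10) stop("could not build non-degenerate CV folds")
    message("degenerate CV fold; refolding with shifted seed")
    set.seed(seed + tries)
    folds <- integer(length(y))
    for (cl in unique(y)) {
      pos <- which(y == cl)
      folds[sample(pos)] <- rep_len(seq_len(n_folds), length(pos))
    }
  }
  aucs <- vapply(sort(unique(folds)), function(k) {
    tr <- folds != k
    model <- fit_method(method, x[tr, , drop = FALSE], y[tr], params, seed)
    s <- predict_method(method, model, x[!tr, , drop = FALSE])
    compute_auc(s, y[!tr])
  }, numeric(1))
  mean(aucs)
}

#' Train one benchmark learner with CV hyperparameter selection
#'
#' Fits one of the three base classification methods on (already scaled)
#' training features. Hyperparameters are chosen by mean cross-validated
#' AUC over the supplied grid; the final model is refit on all training
#' rows with the winning setting. Adaptive boosting is exponentially
#' reweighted decision stumps; gradient boosting is gradient-boosted
#' shallow trees on logistic loss; logistic regression is the
#' maximum-likelihood linear logit.
#'
#' @param method One of `"adaptive_boosting"`, `"gradient_boosting"`,
#'   `"logistic_regression"`.
#' @param x Training feature data.frame (scaled, complete).
#' @param y Binary 0/1 label vector.
#' @param folds Integer fold assignment per training row.
#' @param grid Hyperparameter data.frame (one row per setting); defaults
#'   from [default_hyper_grid()].
#' @param seed Integer seed (controls any stochastic learner internals).
#' @return An object of class `fs_learner` with elements `method`,
#'   `params`, `cv_auc`, and the fitted model; use [predict()] to obtain
#'   probability-like scores in `[0, 1]`.
#' @export
train_learner <- function(method, x, y, folds,
                          grid = default_hyper_grid()[[method]], seed = 1) {
  method <- match.arg(method, CLASSIFIER_METHODS[1:3])
  x <- as.data.frame(x)
  y <- as.integer(as.logical(y))
  cv <- vapply(seq_len(nrow(grid)), function(i) {
    cv_auc(method, x, y, folds, as.list(grid[i, , drop = FALSE]), seed)
  }, numeric(1))
  best <- which.max(cv)  # ties resolve to the first grid row
  params <- as.list(grid[best, , drop = FALSE])
  model <- fit_method(method, x, y, params, seed)
  structure(list(method = method, params = params, cv_auc = cv[best],
                 model = model, features = names(x)),
            class = "fs_learner")
}

#' @export
predict.fs_learner <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[object$features]
  predict_method(object$method, object$model, newdata)
}

#' Train the stacked ensemble
#'
#' Stacking over the three base methods: each base method's
#' hyperparameters are selected by CV, its out-of-fold scores on the
#' training rows become meta-features, and a logistic meta-learner is fit
#' on them. At prediction time, base models refit on the full training set
#' feed the meta-learner.
#'
#' @param x Training feature data.frame (scaled, complete).
#' @param y Binary 0/1 label vector.
#' @param folds Integer fold assignment per training row.
#' @param grids Named list of base-method grids (default
#'   [default_hyper_grid()]).
#' @param seed Integer seed.
#' @return An object of class `fs_ensemble`; use [predict()] for scores.
#' @export
train_ensemble <- function(x, y, folds, grids = default_hyper_grid(),
                           seed = 1) {
  x <- as.data.frame(x)
  y <- as.integer(as.logical(y))
  base_methods <- CLASSIFIER_METHODS[1:3]
  bases <- lapply(base_methods, function(m) {
    train_learner(m, x, y, folds, grid = grids[[m]], seed = seed)
  })
  names(bases) <- base_methods
  oof <- matrix(NA_real_, nrow(x), length(base_methods),
                dimnames = list(NULL, base_methods))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    for (m in base_methods) {
      fit <- fit_method(m, x[tr, , drop = FALSE], y[tr], bases[[m]]$params,
                        seed)
      oof[!tr, m] <- predict_method(m, fit, x[!tr, , drop = FALSE])
    }
  }
  meta_dat <- as.data.frame(oof)
  meta_dat$.y <- y
  meta <- suppressWarnings(stats::glm(.y ~ ., data = meta_dat,
                                      family = stats::binomial()))
  structure(list(bases = bases, meta = meta, features = names(x)),
            class = "fs_ensemble")
}

#' @export
predict.fs_ensemble <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[object$features]
  base_scores <- as.data.frame(lapply(object$bases, predict,
                                      newdata = newdata))
  names(base_scores) <- names(object$bases)
  suppressWarnings(unname(predict(object$meta, newdata = base_scores,
                                  type = "response")))
}
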