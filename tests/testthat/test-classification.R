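test_that("min-max scaling uses training statistics only", {
  sc <- minmax_fit_apply(data.frame(a = c(2, 4, 6), b = c(5, 5, 5)),
                         data.frame(a = c(8, 2), b = c(7, 5)))
  expect_equal(sc$train$a, c(0, 0.5, 1))
  expect_equal(sc$train$b, c(0, 0, 0))       # constant column convention
  expect_equal(sc$test$a, c(1.5, 0))         # outside [0,1], not clipped
  expect_equal(sc$ranges$min, c(2, 5))
  expect_error(minmax_fit_apply(data.frame(a = 1), data.frame(b = 1)), "a")
  # leakage check: pooled-range scaling gives a different transform
  pooled <- minmax_fit_apply(data.frame(a = c(2, 4, 6, 8)))
  expect_false(isTRUE(all.equal(sc$test$a[1],
                                pooled$train$a[4])))
})

test_that("stratified split and folds are exact and seed-deterministic", {
  labels <- rep(c(1, 0), c(10, 90))
  sp <- split_data(labels, seed = 5)
  expect_equal(length(sp$train_idx), 70)
  expect_equal(sum(labels[sp$train_idx]), 7)
  expect_equal(sum(labels[sp$test_idx]), 3)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:100)
  expect_equal(sort(unique(sp$folds)), 1:5)
  expect_equal(length(sp$folds), 70)
  sp2 <- split_data(labels, seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_data(rep(1, 50)), "both classes")
})

test_that("AUC equals pair-counting oracle and known values", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # force some ties
    expect_equal(compute_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(compute_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(33)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.5)
  a <- compute_auc(scores, labels)
  expect_equal(compute_auc(exp(scores), labels), a)
  expect_equal(compute_auc(rank(scores), labels), a)
})

toy_separable <- function(n = 120, seed = 3) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.4)
  data.frame(x1 = y + rnorm(n, 0, 0.05), x2 = rnorm(n), y = y)
}

test_that("learners separate separable data and are seed-deterministic", {
  d <- toy_separable()
  folds <- integer(nrow(d))
  for (cl in 0:1) folds[d$y == cl] <- rep_len(1:5, sum(d$y == cl))
  for (m in c("adaptive_boosting", "gradient_boosting",
              "logistic_regression")) {
    fit <- train_learner(m, d[c("x1", "x2")], d$y, folds, seed = 2)
    expect_equal(compute_auc(predict(fit, d[c("x1", "x2")]), d$y), 1)
    fit2 <- train_learner(m, d[c("x1", "x2")], d$y, folds, seed = 2)
    expect_identical(fit$params, fit2$params)
    expect_equal(predict(fit, d[c("x1", "x2")]),
                 predict(fit2, d[c("x1", "x2")]))
  }
})

test_that("pure-noise features give chance-level CV AUC", {
  set.seed(44)
  aucs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 150
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    y <- rbinom(n, 1, 0.5)
    folds <- rep_len(1:5, n)
    fit <- train_learner("gradient_boosting", d, y, folds, seed = s)
    fit$cv_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("stacking tracks its best base and preserves equal-base ranking", {
  d <- toy_separable(200, seed = 9)
  sp <- split_data(d$y, seed = 9)
  tr <- d[sp$train_idx, ]; te <- d[sp$test_idx, ]
  ens <- train_ensemble(tr[c("x1", "x2")], tr$y, sp$folds, seed = 9)
  expect_gte(compute_auc(predict(ens, te[c("x1", "x2")]), te$y), 0.95)
  # the logistic meta-model of monotone base scores preserves AUC
  base_auc <- compute_auc(predict(ens$bases$logistic_regression,
                                  te[c("x1", "x2")]), te$y)
  expect_gte(compute_auc(predict(ens, te[c("x1", "x2")]), te$y),
             base_auc - 0.05)
  ens2 <- train_ensemble(tr[c("x1", "x2")], tr$y, sp$folds, seed = 9)
  expect_equal(predict(ens, te[c("x1", "x2")]),
               predict(ens2, te[c("x1", "x2")]))
})

test_that("model feature sets follow the five specifications", {
  fn <- feature_names()
  expect_equal(model_feature_set(1), fn$ses)
  expect_setequal(model_feature_set(2), c(fn$ses, fn$nutrients))
  expect_setequal(model_feature_set(3), c(fn$ses, fn$sentiment))
  expect_setequal(model_feature_set(4),
                  c(fn$ses, fn$nutrients, fn$sentiment))
  expect_error(model_feature_set(5), "screen")
  fake_screen <- structure(list(significant = c("mean_cholesterol")),
                           class = "association_screen")
  expect_setequal(model_feature_set(5, fake_screen),
                  c(fn$ses, "mean_cholesterol"))
})
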