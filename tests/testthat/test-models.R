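# synthetic binary classification data with a clean linear signal
.sep_data <- function(n, p = 6, margin = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    y <- as.integer(x[, 1] + x[, 2] > 0)
    x[, 1] <- x[, 1] + margin * (2 * y - 1)   # widen the margin
    list(x = x, y = y)
  })
}

test_that("train/test split is stratified, seeded and exact", {
  d <- .sep_data(100, seed = 2)
  sp <- split_train_test(d$x, d$y, 0.8, seed = 3)
  expect_equal(nrow(sp$train$x), 80)
  expect_equal(nrow(sp$test$x), 20)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp2 <- split_train_test(d$x, d$y, 0.8, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)

  # class proportions within one observation of the overall proportions
  for (cl in 0:1) {
    overall <- mean(d$y == cl)
    expect_lte(abs(mean(sp$train$y == cl) - overall), 1 / 80 + 1e-9)
    expect_lte(abs(mean(sp$test$y == cl) - overall), 1 / 20 + 1e-9)
  }
  expect_error(split_train_test(d$x, d$y, 1.2, 1), "fraction")
})

test_that("all five families separate clean data almost perfectly", {
  d <- .sep_data(240, margin = 3, seed = 4)
  sp <- split_train_test(d$x, d$y, 0.8, seed = 5)
  for (fam in c("lasso", "ridge", "elastic_net", "svm_rbf",
                "random_forest")) {
    ev <- fit_and_score(sp$train, sp$test,
                        model_spec(fam, forest_size = 150, seed = 6))
    expect_gt(ev$test_auc, 0.99)
    expect_true(all(ev$scores >= 0 & ev$scores <= 1))
    expect_equal(ev$roc$fpr[1], 0)
    expect_equal(ev$roc$tpr[1], 0)
    expect_equal(utils::tail(ev$roc$fpr, 1), 1)
    expect_equal(utils::tail(ev$roc$tpr, 1), 1)
  }
})

test_that("the one-standard-error rule never weakens penalization", {
  d <- .sep_data(150, p = 30, margin = 1, seed = 7)
  sp <- split_train_test(d$x, d$y, 0.8, seed = 8)
  for (fam in c("lasso", "ridge", "elastic_net")) {
    ev <- fit_and_score(sp$train, sp$test, model_spec(fam, seed = 9))
    expect_gte(ev$details$lambda_1se, ev$details$lambda_min)
    expect_equal(ev$details$lambda, ev$details$lambda_1se)
  }
})

test_that("permuted labels give chance-level test AUC", {
  d <- .sep_data(800, p = 20, seed = 10)
  y_perm <- withr::with_seed(11, sample(d$y))
  sp <- split_train_test(d$x, y_perm, 0.8, seed = 12)
  for (fam in c("ridge", "random_forest")) {
    ev <- fit_and_score(sp$train, sp$test,
                        model_spec(fam, forest_size = 150, seed = 13))
    expect_gte(ev$test_auc, 0.4)
    expect_lte(ev$test_auc, 0.6)
  }
})

test_that("model fits are reproducible and reject degenerate labels", {
  d <- .sep_data(100, seed = 14)
  sp <- split_train_test(d$x, d$y, 0.8, seed = 15)
  e1 <- fit_and_score(sp$train, sp$test,
                      model_spec("random_forest", forest_size = 80,
                                 seed = 16))
  e2 <- fit_and_score(sp$train, sp$test,
                      model_spec("random_forest", forest_size = 80,
                                 seed = 16))
  expect_identical(e1$scores, e2$scores)

  bad <- list(x = sp$train$x, y = rep(1L, nrow(sp$train$x)))
  expect_error(fit_and_score(bad, sp$test, model_spec("lasso")),
               "single-class")
  y4 <- rep(c("a", "b", "c", "d"), 20)
  expect_error(
    fit_and_score(list(x = sp$train$x, y = y4), sp$test,
                  model_spec("ridge")),
    "random_forest")
})

test_that("ROC AUC equals the Mann-Whitney rank statistic", {
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0, 1, 0, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)

  withr::with_seed(21, {
    for (i in 1:500) {
      n1 <- sample(3:30, 1)
      n0 <- sample(3:30, 1)
      tie <- i %% 3 == 0
      s <- if (tie) sample(1:5, n0 + n1, replace = TRUE) / 5
      else runif(n0 + n1)
      y <- c(rep(0, n0), rep(1, n1))
      u <- sum(rank(s)[y == 1]) - n1 * (n1 + 1) / 2
      expect_equal(roc_auc(s, y)$auc, u / (n0 * n1), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(runif(5), rep(1, 5)), "positive")
})

test_that("Hand-Till AUC reduces to binary and behaves at the extremes", {
  withr::with_seed(22, {
    s <- runif(100)
    y <- rbinom(100, 1, plogis(3 * s - 1.5))
  })
  m <- cbind(`0` = 1 - s, `1` = s)
  expect_equal(hand_till_auc(m, y), roc_auc(s, y)$auc)

  # perfectly separated four classes
  y4 <- rep(c("a", "b", "c", "d"), each = 25)
  m4 <- matrix(0.01, 100, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  m4[cbind(seq_len(100), match(y4, colnames(m4)))] <- 0.97
  expect_equal(hand_till_auc(m4, y4), 1)

  # random scores, four classes: 0.5 within Monte-Carlo noise
  withr::with_seed(23, {
    mr <- matrix(runif(2000 * 4), 2000, 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
    yr <- sample(c("a", "b", "c", "d"), 2000, replace = TRUE)
  })
  expect_lt(abs(hand_till_auc(mr, yr) - 0.5), 0.03)
  expect_error(hand_till_auc(m4, rep("a", 100)), "two classes")
})

test_that("multiclass random forest supports the specialty task", {
  withr::with_seed(24, {
    n <- 400
    x <- matrix(rnorm(n * 5), n, 5)
    y <- c("male", "female", "beauty", "other")[
      max.col(cbind(x[, 1], x[, 2], x[, 3], 0.5 * x[, 4]))]
  })
  sp <- split_train_test(x, y, 0.8, seed = 25)
  ev <- fit_and_score(sp$train, sp$test,
                      model_spec("random_forest", forest_size = 150,
                                 seed = 26))
  expect_gt(ev$hand_till_auc, 0.8)
  expect_gt(ev$accuracy, 0.5)
  expect_equal(sort(colnames(ev$scores)),
               sort(c("male", "female", "beauty", "other")))
})

test_that("ablation removes exactly the tagged columns and finds the signal", {
  fxm <- fx_small_fm()
  fm <- fxm$fm
  ab <- ablation_study(fm, model_spec("random_forest", forest_size = 100,
                                      seed = 27), seed = 28)
  expect_setequal(ab$omitted, c("none", "general", "semantic", "location"))
  for (cc in c("general", "semantic", "location")) {
    expect_equal(ab$n_features[ab$omitted == cc],
                 sum(fm$daywise_category != cc))
  }
  expect_equal(ab$n_features[ab$omitted == "none"], ncol(fm$daywise))
})
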