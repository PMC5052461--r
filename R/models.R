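#' Model specification
#'
#' The five supported families and their tuning protocol: regularized linear
#' families are tuned by k-fold cross-validation over a lambda path with the
#' one-standard-error rule (the largest lambda whose CV error is within one
#' SE of the minimum — penalization never weaker than at the minimum); the
#' elastic net grid-searches alpha as well; the RBF SVM fixes
#' gamma = 1/(number of features) and chooses cost by cross-validation; the
#' random forest uses `forest_size` trees with sqrt(p) features per split.
#'
#' @param family one of `"lasso"`, `"ridge"`, `"elastic_net"`, `"svm_rbf"`,
#'   `"random_forest"`
#' @param cv_folds cross-validation folds (>= 2)
#' @param use_1se apply the one-standard-error lambda rule
#' @param alpha_grid elastic-net alpha grid
#' @param n_lambda lambda path length
#' @param cost_grid SVM cost grid
#' @param forest_size number of trees
#' @param seed integer seed for folds and forest
#' @return a `model_spec` list
#' @export
model_spec <- function(family = c("lasso", "ridge", "elastic_net", "svm_rbf",
                                  "random_forest"),
                       cv_folds = 5L,
                       use_1se = TRUE,
                       alpha_grid = seq(0.1, 0.9, by = 0.2),
                       n_lambda = 50L,
                       cost_grid = 2^(-2:4),
                       forest_size = 200L,
                       seed = 1L) {
  family <- match.arg(family)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  spec <- list(family = family, cv_folds = as.integer(cv_folds),
               use_1se = use_1se, alpha_grid = alpha_grid,
               n_lambda = as.integer(n_lambda), cost_grid = cost_grid,
               forest_size = as.integer(forest_size),
               seed = as.integer(seed))
  class(spec) <- "model_spec"
  spec
}

#' Stratified train/test split
#'
#' User-level, class-stratified, seeded split; class proportions in each part
#' differ from the overall proportions by at most one user per class.
#'
#' @param x feature matrix (users in rows)
#' @param labels class labels aligned with rows
#' @param fraction training fraction in (0, 1)
#' @param seed integer seed
#' @return list with `train` and `test` (each `list(x, y)`), plus the row
#'   indices `train_idx` / `test_idx`
#' @export
split_train_test <- function(x, labels, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  with_seed(seed, {
    idx_tr <- integer()
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      n_tr <- round(fraction * length(rows))
      idx_tr <- c(idx_tr, sample(rows, n_tr))
    }
    idx_tr <- sort(idx_tr)
    idx_te <- setdiff(seq_along(labels), idx_tr)
    list(train = list(x = x[idx_tr, , drop = FALSE], y = labels[idx_tr]),
         test = list(x = x[idx_te, , drop = FALSE], y = labels[idx_te]),
         train_idx = idx_tr, test_idx = idx_te)
  })
}

# stratified fold assignment for cross-validation
.make_foldid <- function(y, k, seed) {
  with_seed(seed, {
    fid <- integer(length(y))
    for (cl in unique(y)) {
      rows <- which(y == cl)
      fid[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    fid
  })
}

.fit_glmnet_family <- function(train, spec) {
  foldid <- .make_foldid(train$y, spec$cv_folds, spec$seed)
  pick_lambda <- function(cv) if (spec$use_1se) cv$lambda.1se else cv$lambda.min
  if (spec$family == "elastic_net") {
    cvs <- lapply(spec$alpha_grid, function(a)
      glmnet::cv.glmnet(train$x, train$y, family = "binomial", alpha = a,
                        foldid = foldid, nlambda = spec$n_lambda))
    best <- which.min(vapply(cvs, function(cv) min(cv$cvm), numeric(1)))
    cv <- cvs[[best]]
    alpha <- spec$alpha_grid[best]
  } else {
    alpha <- if (spec$family == "lasso") 1 else 0
    cv <- glmnet::cv.glmnet(train$x, train$y, family = "binomial",
                            alpha = alpha, foldid = foldid,
                            nlambda = spec$n_lambda)
  }
  list(cv = cv, alpha = alpha, lambda = pick_lambda(cv))
}

.fit_svm_cv <- function(train, spec) {
  foldid <- .make_foldid(train$y, spec$cv_folds, spec$seed)
  gamma <- 1 / ncol(train$x)
  cv_auc <- vapply(spec$cost_grid, function(cost) {
    aucs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- foldid != f
      if (length(unique(train$y[tr])) < 2 ||
          length(unique(train$y[!tr])) < 2) return(NA_real_)
      m <- svm_fit(train$x[tr, , drop = FALSE], train$y[tr],
                   cost = cost, gamma = gamma)
      p <- predict(m, train$x[!tr, , drop = FALSE])
      roc_auc(p, train$y[!tr])$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  cost <- spec$cost_grid[which.max(cv_auc)]
  list(model = svm_fit(train$x, train$y, cost = cost, gamma = gamma),
       cost = cost, gamma = gamma)
}

#' Fit one model family and evaluate on held-out data
#'
#' Runs the family's tuning protocol on the training part only and reports
#' train/test AUC, the test ROC, and per-observation probability scores.
#' For multiclass labels (random forest only) the Hand-Till AUC and argmax
#' accuracy are reported instead of the binary ROC.
#'
#' @param train,test lists with elements `x` (matrix) and `y` (labels), as
#'   produced by [split_train_test()]
#' @param spec a [model_spec()]
#' @return a `geoseek_eval` list: family, train_auc, test_auc, roc, scores,
#'   and tuning details (lambda/alpha or cost); multiclass adds
#'   `hand_till_auc`, `accuracy` and a score matrix
#' @export
fit_and_score <- function(train, test, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  classes <- unique(as.character(train$y))
  if (length(classes) < 2)
    stop("single-class training labels", call. = FALSE)
  multiclass <- length(classes) > 2

  if (multiclass && spec$family != "random_forest")
    stop("multiclass labels are supported by the random_forest family only",
         call. = FALSE)

  details <- list()
  if (spec$family %in% c("lasso", "ridge", "elastic_net")) {
    fit <- .fit_glmnet_family(train, spec)
    score <- function(x) as.numeric(predict(fit$cv, x, s = fit$lambda,
                                            type = "response"))
    details <- list(alpha = fit$alpha, lambda = fit$lambda,
                    lambda_min = fit$cv$lambda.min,
                    lambda_1se = fit$cv$lambda.1se)
  } else if (spec$family == "svm_rbf") {
    fit <- .fit_svm_cv(train, spec)
    score <- function(x) predict(fit$model, x)
    details <- list(cost = fit$cost, gamma = fit$gamma)
  } else {
    rf <- rf_fit(train$x, train$y, n_trees = spec$forest_size,
                 seed = spec$seed)
    if (multiclass) {
      p_tr <- predict(rf, train$x)
      p_te <- predict(rf, test$x)
      pred <- colnames(p_te)[max.col(p_te, ties.method = "first")]
      out <- list(family = spec$family,
                  train_hand_till = hand_till_auc(p_tr, train$y),
                  hand_till_auc = hand_till_auc(p_te, test$y),
                  accuracy = mean(pred == as.character(test$y)),
                  scores = p_te, details = list(mtry = rf$mtry))
      class(out) <- "geoseek_eval"
      return(out)
    }
    pos <- rf$levels[length(rf$levels)]
    score <- function(x) predict(rf, x)[, pos]
    details <- list(mtry = rf$mtry)
  }

  s_tr <- score(train$x)
  s_te <- score(test$x)
  te <- roc_auc(s_te, test$y)
  out <- list(family = spec$family,
              train_auc = roc_auc(s_tr, train$y)$auc,
              test_auc = te$auc, roc = te$roc, scores = s_te,
              details = details)
  class(out) <- "geoseek_eval"
  out
}

#' @export
#' @method print geoseek_eval
print.geoseek_eval <- function(x, ...) {
  if (!is.null(x$test_auc))
    cat(sprintf("<geoseek_eval> %s: train AUC %.3f, test AUC %.3f\n",
                x$family, x$train_auc, x$test_auc))
  else
    cat(sprintf("<geoseek_eval> %s: Hand-Till AUC %.3f, accuracy %.3f\n",
                x$family, x$hand_till_auc, x$accuracy))
  invisible(x)
}

#' Leave-one-feature-category-out ablation
#'
#' Fits the same family on the full daywise matrix and on the three matrices
#' obtained by dropping, in turn, every column of one feature category
#' (general, semantic, location), all on the same train/test split, and
#' reports test AUC per omitted category.
#'
#' @param fm a `feature_matrices` object (tags are taken from
#'   `daywise_category`)
#' @param spec a [model_spec()]
#' @param fraction training fraction
#' @param seed split seed
#' @return `data.table` with columns omitted ("none" = full model),
#'   n_features, test_auc
#' @export
ablation_study <- function(fm, spec = model_spec("random_forest"),
                           fraction = 0.8, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrices"))
  sp <- split_train_test(fm$daywise, fm$labels, fraction, seed)
  cats <- c("none", intersect(c("general", "semantic", "location"),
                              unique(fm$daywise_category)))
  res <- lapply(cats, function(cc) {
    keep <- if (cc == "none") rep(TRUE, ncol(fm$daywise))
    else fm$daywise_category != cc
    tr <- list(x = sp$train$x[, keep, drop = FALSE], y = sp$train$y)
    te <- list(x = sp$test$x[, keep, drop = FALSE], y = sp$test$y)
    ev <- fit_and_score(tr, te, spec)
    data.table::data.table(omitted = cc, n_features = sum(keep),
                           test_auc = ev$test_auc)
  })
  data.table::rbindlist(res)[]
}
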