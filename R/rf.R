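#' Random forest classifier (built-in implementation)
#'
#' A compact bagged-CART forest with Gini splits and per-node feature
#' subsampling, implemented in C++ because no random-forest package is
#' assumed to be installed. Leaves store class distributions; predictions
#' are the across-tree mean of leaf distributions, so scores are
#' probabilities. Multiclass is supported.
#'
#' @param x numeric feature matrix
#' @param y class labels (factor, character or 0/1)
#' @param n_trees number of trees
#' @param mtry features tried per split (default `floor(sqrt(p))`)
#' @param min_node minimum leaf size
#' @param max_depth maximum tree depth
#' @param seed integer seed (the forest has its own RNG)
#' @return a `geoseek_rf` model
#' @export
rf_fit <- function(x, y, n_trees = 200L, mtry = NULL, min_node = 5L,
                   max_depth = 25L, seed = 1L) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("training labels contain a single class",
                           call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  forest <- .rf_grow(x, as.integer(y) - 1L, nlevels(y), as.integer(n_trees),
                     as.integer(mtry), as.integer(min_node),
                     as.integer(max_depth), as.integer(seed))
  out <- list(forest = forest, levels = levels(y), mtry = as.integer(mtry),
              n_trees = as.integer(n_trees))
  class(out) <- "geoseek_rf"
  out
}

#' @param object a `geoseek_rf` model
#' @param newdata numeric matrix with the training columns
#' @param ... unused
#' @return matrix of class probabilities (one column per class)
#' @rdname rf_fit
#' @export
predict.geoseek_rf <- function(object, newdata, ...) {
  p <- .rf_predict(object$forest, newdata, length(object$levels))
  colnames(p) <- object$levels
  p
}
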