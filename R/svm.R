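#' Least-squares SVM with RBF kernel (built-in implementation)
#'
#' A Gaussian-kernel least-squares support vector machine (Suykens form):
#' with kernel matrix K, the dual coefficients solve the linear system
#' \deqn{[0, 1'; 1, K + I/C] [b; alpha] = [0; y]} with y in \{-1, +1\}.
#' Decision values are mapped to probabilities by Platt-style logistic
#' calibration on the training decision values. Implemented directly because
#' no SVM package is assumed installed; `gamma` defaults to 1/p per the
#' standard heuristic.
#'
#' @param x numeric feature matrix
#' @param y binary labels (0/1, logical or 2-level factor)
#' @param cost regularization parameter C (> 0)
#' @param gamma RBF width; default 1 / ncol(x)
#' @return a `geoseek_svm` model
#' @export
svm_fit <- function(x, y, cost = 1, gamma = NULL) {
  y <- as.integer(factor(y)) - 1L
  if (length(unique(y)) != 2) stop("labels must contain exactly two classes",
                                   call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  yy <- ifelse(y == 1, 1, -1)
  K <- .rbf_kernel(x, x, gamma)
  n <- nrow(x)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / cost, n)))
  sol <- solve(A, c(0, yy))
  b <- sol[1]
  alpha <- sol[-1]
  dec <- as.numeric(K %*% alpha + b)
  platt <- suppressWarnings(glm(y ~ dec, family = binomial()))
  out <- list(x = x, alpha = alpha, b = b, gamma = gamma, cost = cost,
              platt = coef(platt))
  class(out) <- "geoseek_svm"
  out
}

.rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' @param object a `geoseek_svm` model
#' @param newdata numeric matrix
#' @param type `"prob"` (default) or `"decision"`
#' @param ... unused
#' @rdname svm_fit
#' @export
predict.geoseek_svm <- function(object, newdata,
                                type = c("prob", "decision"), ...) {
  type <- match.arg(type)
  K <- .rbf_kernel(newdata, object$x, object$gamma)
  dec <- as.numeric(K %*% object$alpha + object$b)
  if (type == "decision") return(dec)
  plogis(object$platt[1] + object$platt[2] * dec)
}
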