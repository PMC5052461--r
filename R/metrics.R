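#' ROC curve and AUC
#'
#' The ROC is traced over distinct score thresholds (tied scores move the
#' curve diagonally in one step) from (0, 0) to (1, 1); the AUC is the
#' trapezoid area under it, which equals the rank-based Mann-Whitney
#' statistic U / (n1 n2) with average ranks for ties.
#'
#' @param scores numeric scores, higher = more positive
#' @param labels 0/1 (or logical) class labels
#' @return list with `auc` and `roc` (`data.table` of fpr, tpr)
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # end of each tie group
  tpr <- c(0, cumsum(y)[last] / n_pos)
  fpr <- c(0, cumsum(1 - y)[last] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.table::data.table(fpr = fpr, tpr = tpr))
}

#' Hand-Till multiclass AUC
#'
#' The average over unordered class pairs (i, j) of
#' \eqn{[A(i|j) + A(j|i)]/2}, where \eqn{A(i|j)} is the binary AUC of the
#' class-i score restricted to observations of classes i and j. With two
#' classes this reduces exactly to the binary AUC.
#'
#' @param score_matrix numeric matrix, one column per class (columns named
#'   by class)
#' @param labels class labels matching the column names
#' @return the multiclass AUC
#' @export
hand_till_auc <- function(score_matrix, labels) {
  classes <- colnames(score_matrix)
  if (is.null(classes)) stop("score_matrix needs class column names",
                             call. = FALSE)
  present <- intersect(classes, unique(as.character(labels)))
  if (length(present) < 2) stop("need at least two classes present",
                                call. = FALSE)
  labels <- as.character(labels)
  pair_auc <- function(i, j) {
    keep <- labels %in% c(i, j)
    a_ij <- roc_auc(score_matrix[keep, i], as.integer(labels[keep] == i))$auc
    a_ji <- roc_auc(score_matrix[keep, j], as.integer(labels[keep] == j))$auc
    (a_ij + a_ji) / 2
  }
  pairs <- utils::combn(present, 2)
  mean(vapply(seq_len(ncol(pairs)),
              function(k) pair_auc(pairs[1, k], pairs[2, k]), numeric(1)))
}
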