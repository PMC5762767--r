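#' K-nearest-neighbour multi-label scores
#'
#' Binary-relevance adaptation of KNN to multi-label ranking: the score of
#' label `l` for a query is the fraction of the query's `k` Euclidean
#' nearest training instances whose label set contains `l`. Distance ties
#' are broken by training-instance index, so the baseline is fully
#' deterministic.
#'
#' @param train A [multilabel_dataset()] of training instances.
#' @param X Query feature matrix (same columns as the training features).
#' @param k Number of neighbours, `1 <= k <=` training size.
#' @return A [ranked_prediction()].
#' @export
knn_scores <- function(train, X, k = 10) {
  stopifnot(inherits(train, "multilabel_dataset"))
  Tr <- train$features
  X <- if (inherits(X, "multilabel_dataset")) X$features else as.matrix(X)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(Tr)) stop("k exceeds the number of training instances")
  n <- length(train$label_names)
  Ymat <- label_matrix(train) * 1
  # squared Euclidean distances query x train, computed blockwise
  d2 <- outer(rowSums(X^2), rowSums(Tr^2), "+") - 2 * tcrossprod(X, Tr)
  scores <- t(vapply(seq_len(nrow(X)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]   # order() breaks ties by index
    colSums(Ymat[nb, , drop = FALSE]) / k
  }, numeric(n)))
  ranked_prediction(scores, label_names = train$label_names)
}

#' Decision-tree multi-label scores
#'
#' Binary-relevance adaptation of axis-aligned classification trees: one
#' tree per label, grown greedily on the Gini criterion (via `rpart`),
#' stopped at `maxdepth` or purity with at least `minbucket` instances per
#' leaf; the score of label `l` for a query is the positive fraction in the
#' leaf the query reaches. A label constant in training yields its constant
#' prevalence (0 or 1). Deterministic: no randomness is involved.
#'
#' @param train A [multilabel_dataset()].
#' @param X Query feature matrix.
#' @param maxdepth Maximum tree depth (default 30, `rpart`'s limit, i.e.
#'   effectively unlimited).
#' @param minbucket Minimum instances in a leaf (default 2).
#' @return A [ranked_prediction()].
#' @export
dt_scores <- function(train, X, maxdepth = 30, minbucket = 2) {
  stopifnot(inherits(train, "multilabel_dataset"))
  if (maxdepth < 1) stop("maxdepth must be >= 1")
  X <- if (inherits(X, "multilabel_dataset")) X$features else as.matrix(X)
  Tr <- train$features
  n <- length(train$label_names)
  Ymat <- label_matrix(train)
  df_tr <- as.data.frame(Tr)
  names(df_tr) <- paste0("f", seq_len(ncol(Tr)))
  df_q <- as.data.frame(X)
  names(df_q) <- names(df_tr)
  ctrl <- rpart::rpart.control(cp = 0, xval = 0, maxdepth = maxdepth,
                               minbucket = minbucket,
                               minsplit = 2 * minbucket)
  scores <- vapply(seq_len(n), function(j) {
    y <- factor(ifelse(Ymat[, j], "1", "0"), levels = c("0", "1"))
    if (length(unique(y)) == 1L) {
      return(rep(mean(Ymat[, j]), nrow(X)))
    }
    fit <- rpart::rpart(y ~ ., data = cbind(y = y, df_tr), method = "class",
                        control = ctrl)
    unname(predict(fit, newdata = df_q, type = "prob")[, "1"])
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) scores <- matrix(scores, nrow = 1)
  ranked_prediction(scores, label_names = train$label_names)
}
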