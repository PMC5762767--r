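#' Ranked prediction container
#'
#' Real-valued per-label relevance scores for a set of instances (larger
#' means more relevant), together with a deterministic rank function: rank 1
#' is the highest score, and ties are broken by ascending label index so
#' every instance's ranks are a permutation of `1..N` even for constant
#' scores.
#'
#' @param scores `m x N` numeric matrix.
#' @param label_names Optional `N` label names.
#' @return Object of class `ranked_prediction`.
#' @export
ranked_prediction <- function(scores, label_names = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(label_names)) colnames(scores) <- label_names
  structure(list(scores = scores,
                 label_names = label_names %||% colnames(scores)),
            class = "ranked_prediction")
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat(sprintf("ranked_prediction: %d instances x %d labels\n",
              nrow(x$scores), ncol(x$scores)))
  print(head(x$scores, 3))
  if (nrow(x$scores) > 3) cat("...\n")
  invisible(x)
}

#' Deterministic label ranks
#'
#' For each row of scores, the rank of label `l` is 1 plus the number of
#' labels with strictly greater score plus the number of tied labels with a
#' smaller index — a deterministic total order under which all-equal scores
#' yield ranks `1..N` in index order.
#'
#' @param scores Numeric vector (one instance) or `m x N` matrix.
#' @return Integer vector or matrix of ranks, each row a permutation of
#'   `1..N`.
#' @export
label_ranks <- function(scores) {
  if (is.matrix(scores)) {
    return(t(apply(scores, 1, function(s) rank(-s, ties.method = "first"))))
  }
  as.integer(rank(-scores, ties.method = "first"))
}

#' Rank of one label
#'
#' @param scores Score vector for one instance.
#' @param l Label index in `1..N`.
#' @return Integer rank in `1..N` under the deterministic tie-break of
#'   [label_ranks()].
#' @export
rank_of <- function(scores, l) {
  n <- length(scores)
  if (l < 1 || l > n) stop("label index out of range 1..", n)
  label_ranks(scores)[l]
}

check_proper_labels <- function(labels, n, need_proper = TRUE) {
  for (i in seq_along(labels)) {
    y <- labels[[i]]
    if (length(y) == 0L) {
      stop("degenerate label set at instance ", i,
           ": empty Y is not allowed by the ranking metrics")
    }
    if (need_proper && length(y) == n) {
      stop("degenerate label set at instance ", i,
           ": Y equals the full label universe")
    }
  }
}

resolve_pred <- function(pred) {
  if (inherits(pred, "ranked_prediction")) pred$scores else as.matrix(pred)
}

resolve_labels <- function(labels) {
  if (inherits(labels, "multilabel_dataset")) labels$labels else labels
}

#' Coverage
#'
#' How far down the ranked label list one must go, on average, to cover all
#' of an instance's true labels: the mean over instances of the worst
#' (maximum) rank among the relevant labels, minus one. Lower is better;
#' bounded by `N - 1`.
#'
#' @param pred A [ranked_prediction()] or score matrix.
#' @param labels List of label-index vectors or a [multilabel_dataset()].
#' @return Non-negative scalar, at most `N - 1`.
#' @export
coverage <- function(pred, labels) {
  S <- resolve_pred(pred); labels <- resolve_labels(labels)
  check_proper_labels(labels, ncol(S), need_proper = FALSE)
  R <- label_ranks(S)
  mean(vapply(seq_len(nrow(S)),
              function(i) max(R[i, labels[[i]]]), numeric(1))) - 1
}

#' Ranking loss
#'
#' The mean over instances of the fraction of (relevant, irrelevant) label
#' pairs that are mis-ordered, where a tie `f(y1) = f(y2)` counts as a
#' violation (the pessimistic reading of `<=`). Zero is perfect ranking.
#'
#' @inheritParams coverage
#' @return Scalar in `[0, 1]`.
#' @export
ranking_loss <- function(pred, labels) {
  S <- resolve_pred(pred); labels <- resolve_labels(labels)
  n <- ncol(S)
  check_proper_labels(labels, n)
  mean(vapply(seq_len(nrow(S)), function(i) {
    y <- labels[[i]]; yb <- setdiff(seq_len(n), y)
    sum(outer(S[i, y], S[i, yb], "<=")) / (length(y) * length(yb))
  }, numeric(1)))
}

#' Average precision (label-ranking form)
#'
#' For each relevant label, the fraction of labels ranked at or above it
#' that are themselves relevant, averaged over the instance's relevant
#' labels and then over instances. One is perfect; larger is better.
#'
#' @inheritParams coverage
#' @return Scalar in `(0, 1]`.
#' @export
average_precision <- function(pred, labels) {
  S <- resolve_pred(pred); labels <- resolve_labels(labels)
  check_proper_labels(labels, ncol(S), need_proper = FALSE)
  R <- label_ranks(S)
  mean(vapply(seq_len(nrow(S)), function(i) {
    y <- labels[[i]]
    ry <- R[i, y]
    mean(vapply(ry, function(r) sum(ry <= r) / r, numeric(1)))
  }, numeric(1)))
}

#' Evaluate all three ranking metrics
#'
#' @inheritParams coverage
#' @return Object of class `metrics_report` with `coverage`, `ranking_loss`,
#'   `average_precision` and the instance count `m`.
#' @export
evaluate_ranking <- function(pred, labels) {
  S <- resolve_pred(pred); labels <- resolve_labels(labels)
  structure(list(coverage = coverage(S, labels),
                 ranking_loss = ranking_loss(S, labels),
                 average_precision = average_precision(S, labels),
                 m = nrow(S)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report (m = %d):\n",
                     "  average precision: %.4f\n",
                     "  ranking loss:      %.4f\n",
                     "  coverage:          %.4f\n"),
              x$m, x$average_precision, x$ranking_loss, x$coverage))
  invisible(x)
}
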