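#' Construct a multi-label dataset
#'
#' The core container shared by every stage: an `m x d` feature matrix with
#' values in `[0, 1]` (term frequencies scaled to the unit interval) and, for
#' each instance, a non-empty subset of a finite label universe (pathway
#' membership). Labels are stored as 1-based integer indices into
#' `label_names`; serialized files always use label names, not indices.
#'
#' @param features Numeric matrix, `m` instances by `d` features, values in
#'   `[0, 1]`.
#' @param labels List of length `m`; each element the labels of one instance,
#'   either integer indices into `label_names` or a character vector of label
#'   names.
#' @param label_names Character vector naming the label universe.
#' @param feature_names,instance_ids Optional character vectors; default to
#'   the matrix dimnames or generated identifiers.
#' @param validate If `TRUE` (default), stop when [validate_dataset()] reports
#'   violations.
#' @return An object of class `multilabel_dataset` with elements `features`,
#'   `labels` (list of sorted integer vectors), `label_names`,
#'   `feature_names`, `instance_ids`.
#' @seealso [validate_dataset()], [rescale_features()], [generate_dataset()]
#' @export
multilabel_dataset <- function(features, labels, label_names,
                               feature_names = NULL, instance_ids = NULL,
                               validate = TRUE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  m <- nrow(features)
  d <- ncol(features)
  feature_names <- feature_names %||% colnames(features) %||%
    sprintf("t%04d", seq_len(d))
  instance_ids <- instance_ids %||% rownames(features) %||%
    sprintf("g%04d", seq_len(m))
  label_names <- as.character(label_names)
  labels <- lapply(labels, function(y) {
    if (is.character(y)) {
      idx <- match(y, label_names)
      if (anyNA(idx)) {
        stop("unknown label name(s): ",
             paste(y[is.na(idx)], collapse = ", "))
      }
      y <- idx
    }
    sort(unique(as.integer(y)))
  })
  dimnames(features) <- list(instance_ids, feature_names)
  ds <- structure(
    list(features = features, labels = labels, label_names = label_names,
         feature_names = feature_names, instance_ids = instance_ids),
    class = "multilabel_dataset")
  if (validate) {
    v <- validate_dataset(ds)
    if (length(v)) stop("invalid dataset:\n  ", paste(v, collapse = "\n  "))
  }
  ds
}

#' Validate a multi-label dataset
#'
#' Checks every container invariant and reports violations rather than
#' throwing: all feature values in `[0, 1]`, every label set non-empty and a
#' subset of the label universe, and consistent instance counts.
#'
#' @param ds A [multilabel_dataset()].
#' @return Character vector of violation descriptions, one per violated
#'   invariant, naming the offending instance or cell; empty when all
#'   invariants hold.
#' @export
validate_dataset <- function(ds) {
  out <- character()
  X <- ds$features
  if (length(ds$labels) != nrow(X)) {
    out <- c(out, sprintf(
      "instance count mismatch: %d feature rows vs %d label rows",
      nrow(X), length(ds$labels)))
  }
  bad <- which(!is.finite(X) | X < 0 | X > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    for (r in seq_len(min(nrow(bad), 10L))) {
      out <- c(out, sprintf(
        "feature value out of [0,1] at instance %d ('%s'), feature %d ('%s'): %g",
        bad[r, 1], ds$instance_ids[bad[r, 1]],
        bad[r, 2], ds$feature_names[bad[r, 2]],
        X[bad[r, 1], bad[r, 2]]))
    }
    if (nrow(bad) > 10L) {
      out <- c(out, sprintf("... and %d further out-of-range cells",
                            nrow(bad) - 10L))
    }
  }
  n_lab <- length(ds$label_names)
  for (i in seq_along(ds$labels)) {
    y <- ds$labels[[i]]
    if (length(y) == 0L) {
      out <- c(out, sprintf("empty label set at instance %d ('%s')",
                            i, ds$instance_ids[i]))
    } else if (any(y < 1L | y > n_lab)) {
      out <- c(out, sprintf(
        "label index outside universe 1..%d at instance %d ('%s')",
        n_lab, i, ds$instance_ids[i]))
    }
  }
  out
}

#' @export
print.multilabel_dataset <- function(x, ...) {
  cat(sprintf(
    "multilabel_dataset: %d instances x %d features, %d labels\n",
    nrow(x$features), ncol(x$features), length(x$label_names)))
  cat(sprintf("  sparsity (exact zeros): %.1f%%\n",
              100 * mean(x$features == 0)))
  cat(sprintf("  mean labels/instance: %.2f\n",
              mean(lengths(x$labels))))
  invisible(x)
}

#' Rescale raw counts column-wise into the unit interval
#'
#' Convenience scaling for raw term counts: each column is divided by its
#' maximum; all-zero columns are left at zero. The encoder requires inputs in
#' `[0, 1]^d`.
#'
#' @param X Non-negative numeric matrix.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
rescale_features <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("rescale_features expects non-negative values")
  cm <- apply(X, 2, max)
  cm[cm == 0] <- 1
  sweep(X, 2, cm, "/")
}

# m x N logical indicator of label membership.
label_matrix <- function(ds) {
  n <- length(ds$label_names)
  t(vapply(ds$labels, function(y) {
    z <- logical(n); z[y] <- TRUE; z
  }, logical(n)))
}

# Instances whose label set is the full universe: the pairwise error is
# undefined there (empty complement) and training/metrics must skip or
# reject them.
degenerate_instances <- function(labels, n_labels) {
  which(lengths(labels) == n_labels)
}
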