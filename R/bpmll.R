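#' Initialize a BP-MLL network
#'
#' A single-hidden-layer feed-forward network for multi-label ranking:
#' hidden `b = s(t(V) x + gamma)`, output `c = s(t(W) b + theta)` with the
#' logistic sigmoid `s`. Weights are initialized uniformly on `+/- 0.05`
#' from the current RNG stream; biases start at zero.
#'
#' @param d Input dimension.
#' @param M Hidden units (`>= 1`).
#' @param n_labels Output units `N` (`>= 2`).
#' @param init_range Half-width of the uniform weight initialization.
#' @return An object of class `bpmll_network` with `V` (`d x M`), `W`
#'   (`M x N`), `gamma` (`M`), `theta` (`N`).
#' @export
bpmll_network <- function(d, M, n_labels, init_range = 0.05) {
  stopifnot(M >= 1, n_labels >= 2)
  structure(
    list(V = matrix(runif(d * M, -init_range, init_range), nrow = d),
         W = matrix(runif(M * n_labels, -init_range, init_range), nrow = M),
         gamma = numeric(M), theta = numeric(n_labels),
         d = as.integer(d), M = as.integer(M),
         n_labels = as.integer(n_labels)),
    class = "bpmll_network")
}

#' Forward pass of a BP-MLL network
#'
#' @param net A [bpmll_network()].
#' @param x Input vector of length `d`.
#' @return List with `hidden` (length `M`) and `output` (length `N`), both
#'   strictly inside `(0, 1)`.
#' @export
bpmll_forward <- function(net, x) {
  if (length(x) != net$d) stop("bpmll_forward: expected input of length ",
                               net$d)
  h <- sigmoid(drop(crossprod(net$V, x)) + net$gamma)
  list(hidden = h, output = sigmoid(drop(crossprod(net$W, h)) + net$theta))
}

#' Pairwise exponential error of one instance
#'
#' The multi-label ranking error for one instance: the mean over all
#' (relevant, irrelevant) label pairs of `exp(-(c_k - c_l))`, i.e.
#' `(1 / (|Y| |Ybar|)) * sum exp(-(c_k - c_l))`. It penalizes any irrelevant
#' label scored near or above a relevant one. Undefined when `Y` is empty or
#' the full label set (the complement is empty); such degenerate label sets
#' are rejected.
#'
#' @param scores Output vector `c` of length `N`.
#' @param Y Integer indices of the instance's relevant labels.
#' @return Positive scalar error.
#' @export
bpmll_instance_error <- function(scores, Y) {
  n <- length(scores)
  Y <- sort(unique(as.integer(Y)))
  if (length(Y) == 0L) {
    stop("degenerate label set: empty Y (the pairwise error needs at least ",
         "one relevant label)")
  }
  if (length(Y) == n) {
    stop("degenerate label set: Y is the full label universe, so its ",
         "complement is empty and the pairwise error is undefined")
  }
  Yb <- setdiff(seq_len(n), Y)
  sum(exp(-outer(scores[Y], scores[Yb], "-"))) / (length(Y) * length(Yb))
}

#' Global pairwise exponential error over a dataset
#'
#' Sum of [bpmll_instance_error()] over all usable instances. Instances with
#' a degenerate label set (full label universe) are skipped, counted, and
#' reported via the `"skipped"` attribute and a message.
#'
#' @param net A [bpmll_network()].
#' @param X Feature/code matrix, `m x d`.
#' @param labels List of label-index vectors, length `m`.
#' @return Scalar total error with attribute `skipped` (count of skipped
#'   degenerate instances).
#' @export
bpmll_global_error <- function(net, X, labels) {
  X <- as.matrix(X)
  n <- net$n_labels
  C <- bpmll_scores(net, X)
  deg <- degenerate_instances(labels, n)
  use <- setdiff(seq_len(nrow(X)), deg)
  if (length(deg)) {
    message("bpmll_global_error: skipping ", length(deg),
            " instance(s) with full label set")
  }
  E <- 0
  for (i in use) E <- E + bpmll_instance_error(C[i, ], labels[[i]])
  attr(E, "skipped") <- length(deg)
  E
}

# Matrix forward pass: scores for all rows of X.
bpmll_scores <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$d) stop("expected ", net$d, " feature columns, got ",
                             ncol(X))
  H <- sigmoid(sweep(X %*% net$V, 2, net$gamma, "+"))
  sigmoid(sweep(H %*% net$W, 2, net$theta, "+"))
}

#' Online gradient updates for one instance
#'
#' Returns the additive parameter updates `Delta = alpha * {d_j b_s,
#' e_s a_h, d_j, e_s}` of the pairwise exponential error for one training
#' instance, with `d_j = -dE_i/d(net c_j)` and `e_s = -dE_i/d(net b_s)`
#' obtained by the chain rule through the sigmoid activations:
#' for a relevant label `j`, `d_j` aggregates `exp(-(c_j - c_l))` over
#' irrelevant `l` (pushing `c_j` up); for an irrelevant `j` it aggregates
#' `-exp(-(c_k - c_j))` over relevant `k` (pushing `c_j` down); both scaled
#' by `c_j (1 - c_j) / (|Y| |Ybar|)`, and
#' `e_s = (sum_j d_j w_sj) b_s (1 - b_s)`.
#' Updates are exactly linear in `alpha`.
#'
#' @param net A [bpmll_network()].
#' @param x Input vector.
#' @param Y Relevant label indices (non-degenerate).
#' @param alpha Learning rate.
#' @return List with updates `V`, `W`, `gamma`, `theta` (add them to the
#'   parameters) plus the forward `output` and the instance `error`.
#' @export
bpmll_gradients <- function(net, x, Y, alpha = 0.05) {
  n <- net$n_labels
  Y <- sort(unique(as.integer(Y)))
  if (length(Y) == 0L || length(Y) == n) {
    stop("degenerate label set: Y must be a non-empty proper subset of ",
         "the label universe")
  }
  fw <- bpmll_forward(net, x)
  cvec <- fw$output; b <- fw$hidden
  Yb <- setdiff(seq_len(n), Y)
  z <- 1 / (length(Y) * length(Yb))
  dj <- numeric(n)
  s_irr <- sum(exp(cvec[Yb]))
  s_rel <- sum(exp(-cvec[Y]))
  dj[Y] <- z * exp(-cvec[Y]) * s_irr * cvec[Y] * (1 - cvec[Y])
  dj[Yb] <- -z * exp(cvec[Yb]) * s_rel * cvec[Yb] * (1 - cvec[Yb])
  es <- drop(net$W %*% dj) * b * (1 - b)
  list(W = alpha * tcrossprod(b, dj),
       theta = alpha * dj,
       V = alpha * tcrossprod(x, es),
       gamma = alpha * es,
       output = cvec,
       error = bpmll_instance_error(cvec, Y))
}

#' Train a BP-MLL network online
#'
#' Feeds the training instances to the network one by one in a per-epoch
#' shuffled order, applying the [bpmll_gradients()] updates. After each
#' epoch the global error `E` is computed on the clean training set; training
#' stops when `E` has not decreased (strictly, beyond `tol`) for `patience`
#' consecutive epochs, or at `max_epochs`. Instances whose label set is the
#' full universe are skipped (with a message). Deterministic given `seed`.
#'
#' @param X `m x d` training matrix (raw features or encoder codes).
#' @param labels List of label-index vectors, length `m`.
#' @param n_labels Size `N` of the label universe.
#' @param M Hidden units.
#' @param alpha Learning rate in `[0, 1)`.
#' @param max_epochs Epoch threshold.
#' @param patience Consecutive non-decreasing epochs tolerated before
#'   stopping.
#' @param tol Decrease below `tol` counts as "not decreased".
#' @param seed Integer seed (initialization and shuffling).
#' @return An object of class `bpmll` with the trained `network`, the
#'   per-epoch global-error `trace`, `epochs_run`, the count of `skipped`
#'   degenerate instances, and the configuration.
#' @export
train_bpmll <- function(X, labels, n_labels, M = 32, alpha = 0.05,
                        max_epochs = 50, patience = 3, tol = 1e-9,
                        seed = 1) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  stopifnot(max_epochs >= 1, patience >= 1)
  X <- as.matrix(X)
  deg <- degenerate_instances(labels, n_labels)
  use <- setdiff(seq_len(nrow(X)), deg)
  if (length(deg)) {
    message("train_bpmll: skipping ", length(deg),
            " instance(s) with full label set")
  }
  if (!length(use)) stop("no usable (non-degenerate) training instances")
  Xu <- X[use, , drop = FALSE]
  labu <- labels[use]
  net0 <- withr::with_seed(stream_seed(seed, "init"),
                           bpmll_network(ncol(X), M, n_labels))
  orders <- withr::with_seed(stream_seed(seed, "shuffle"),
                             shuffle_orders(nrow(Xu), max_epochs))
  rel <- lapply(labu, as.integer)
  irr <- lapply(labu, function(y) setdiff(seq_len(n_labels), y))
  fit <- bpmll_train_cpp(Xu, net0$V, net0$W, net0$gamma, net0$theta,
                         rel, irr, orders, alpha, as.integer(max_epochs),
                         as.integer(patience), tol)
  net <- net0
  net$V <- fit$V; net$W <- fit$W
  net$gamma <- drop(fit$gamma); net$theta <- drop(fit$theta)
  structure(list(network = net, trace = drop(fit$trace),
                 epochs_run = length(fit$trace), skipped = length(deg),
                 config = list(M = M, alpha = alpha, max_epochs = max_epochs,
                               patience = patience, tol = tol, seed = seed)),
            class = "bpmll")
}

#' @export
print.bpmll <- function(x, ...) {
  cat(sprintf("bpmll: %d -> %d -> %d, trained %d epoch(s), final E = %.4f\n",
              x$network$d, x$network$M, x$network$n_labels, x$epochs_run,
              x$trace[length(x$trace)]))
  invisible(x)
}

#' Score instances with a BP-MLL network
#'
#' @param net A [bpmll_network()] (or a trained `bpmll` object).
#' @param X Matrix with `d` columns.
#' @param label_names Optional label names for the prediction object.
#' @return A [ranked_prediction()] holding the `m x N` score matrix.
#' @export
predict_scores <- function(net, X, label_names = NULL) {
  if (inherits(net, "bpmll")) net <- net$network
  ranked_prediction(bpmll_scores(net, X), label_names = label_names)
}

#' Convert ranked scores to label sets
#'
#' The ranking metrics need no thresholds; set-valued output is a
#' convenience. The `"threshold"` rule predicts label `l` iff its score
#' exceeds 0.5 (an empty prediction is allowed and reported with a message);
#' the `"topk"` rule takes the `t` best-ranked labels.
#'
#' @param rp A [ranked_prediction()].
#' @param rule `"threshold"` (default) or `"topk"`.
#' @param t Number of labels for `"topk"`; typically the dataset's rounded
#'   mean label cardinality.
#' @param threshold Score cutoff for the threshold rule.
#' @return List of integer label-index vectors, one per instance.
#' @export
predict_labels <- function(rp, rule = c("threshold", "topk"), t = NULL,
                           threshold = 0.5) {
  rule <- match.arg(rule)
  S <- rp$scores
  if (rule == "threshold") {
    out <- lapply(seq_len(nrow(S)), function(i) which(S[i, ] > threshold))
    if (any(lengths(out) == 0L)) {
      message("predict_labels: ", sum(lengths(out) == 0L),
              " instance(s) received an empty label set under the ",
              "threshold rule")
    }
    out
  } else {
    if (is.null(t)) stop("rule = 'topk' needs t")
    R <- label_ranks(S)
    lapply(seq_len(nrow(S)), function(i) sort(which(R[i, ] <= t)))
  }
}
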