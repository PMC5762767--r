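#' Specify a synthetic multi-label term-frequency dataset
#'
#' Describes a generator that emulates the statistical structure of a
#' literature-mined gene-by-term matrix: sparse non-negative term
#' frequencies in which each pathway label induces an enriched "signature"
#' term set, and each gene (instance) carries one to a few pathway labels.
#' Counts are Poisson: mean `signal_strength` at (instance, term) cells where
#' the term is a signature term of a label the instance owns, mean
#' `background_rate` elsewhere; counts are then rescaled column-wise to
#' `[0, 1]`.
#'
#' @param n_instances Number of instances (genes), `m`.
#' @param n_labels Number of labels (pathways), `N >= 2`.
#' @param n_terms Number of features (terms), `d`.
#' @param signature_terms_per_label Signature terms owned by each label;
#'   signature sets are disjoint across labels unless `signature_overlap > 0`.
#' @param labels_per_instance Integer vector of allowed label-set
#'   cardinalities, sampled uniformly per instance; every value must lie in
#'   `1..N-1` (never `N`, which would make the pairwise error undefined).
#'   Default `c(1, 2, 3)`.
#' @param signal_strength Expected count at signature cells of owned labels.
#' @param background_rate Expected count elsewhere; must satisfy
#'   `signal_strength >= background_rate >= 0`.
#' @param signature_overlap Fraction in `[0, 1)` of each label's signature
#'   terms shared with the next label's set (default 0: disjoint).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_instances, n_labels, n_terms,
                           signature_terms_per_label = 25,
                           labels_per_instance = c(1, 2, 3),
                           signal_strength = 5, background_rate = 0.05,
                           signature_overlap = 0, seed = 1) {
  spec <- structure(
    list(n_instances = as.integer(n_instances),
         n_labels = as.integer(n_labels),
         n_terms = as.integer(n_terms),
         signature_terms_per_label = as.integer(signature_terms_per_label),
         labels_per_instance = as.integer(labels_per_instance),
         signal_strength = as.numeric(signal_strength),
         background_rate = as.numeric(background_rate),
         signature_overlap = as.numeric(signature_overlap),
         seed = as.integer(seed)),
    class = "synthetic_spec")
  err <- validate_spec(spec)
  if (length(err)) stop("invalid synthetic_spec: ", paste(err, collapse = "; "))
  spec
}

validate_spec <- function(spec) {
  err <- character()
  if (spec$n_labels < 2L) err <- c(err, "n_labels must be >= 2")
  if (spec$n_instances < 1L) err <- c(err, "n_instances must be >= 1")
  if (spec$signature_terms_per_label * spec$n_labels > spec$n_terms) {
    err <- c(err,
             "signature_terms_per_label * n_labels must be <= n_terms")
  }
  if (!(spec$signal_strength >= spec$background_rate &&
        spec$background_rate >= 0)) {
    err <- c(err, "need signal_strength >= background_rate >= 0")
  }
  if (any(spec$labels_per_instance < 1L) ||
      any(spec$labels_per_instance > spec$n_labels - 1L)) {
    err <- c(err, "labels_per_instance values must lie in 1..n_labels-1")
  }
  if (spec$signature_overlap < 0 || spec$signature_overlap >= 1) {
    err <- c(err, "signature_overlap must be in [0, 1)")
  }
  err
}

#' Generate a synthetic multi-label term-frequency dataset
#'
#' Draws a dataset according to a [synthetic_spec()]: each instance samples
#' its label-set size uniformly from `labels_per_instance`, then its labels
#' uniformly without replacement; Poisson counts are drawn with mean
#' `signal_strength` at signature cells of owned labels and
#' `background_rate` elsewhere, then rescaled column-wise to `[0, 1]`.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A valid [multilabel_dataset()]; the signature term indices per
#'   label are attached as attribute `"signature_terms"`.
#' @export
generate_dataset <- function(spec) {
  err <- validate_spec(spec)
  if (length(err)) stop("invalid synthetic_spec: ", paste(err, collapse = "; "))
  withr::with_seed(spec$seed, {
    m <- spec$n_instances; n <- spec$n_labels; d <- spec$n_terms
    s <- spec$signature_terms_per_label
    # signature blocks: label j owns terms in a contiguous block; with
    # overlap > 0 the first ceil(overlap*s) terms are shared with label j-1.
    shift <- s - ceiling(spec$signature_overlap * s)
    sig <- lapply(seq_len(n), function(j) ((j - 1L) * shift) + seq_len(s))
    labels <- lapply(seq_len(m), function(i) {
      k <- if (length(spec$labels_per_instance) == 1L) {
        spec$labels_per_instance
      } else {
        sample(spec$labels_per_instance, 1L)
      }
      sort(sample.int(n, k))
    })
    counts <- matrix(rpois(m * d, spec$background_rate), nrow = m, ncol = d)
    for (i in seq_len(m)) {
      cells <- unique(unlist(sig[labels[[i]]]))
      counts[i, cells] <- rpois(length(cells), spec$signal_strength)
    }
    X <- rescale_features(counts)
    ds <- multilabel_dataset(
      X, labels, label_names = sprintf("P%02d", seq_len(n)),
      feature_names = sprintf("t%05d", seq_len(d)),
      instance_ids = sprintf("g%05d", seq_len(m)))
    attr(ds, "signature_terms") <- sig
    ds
  })
}
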