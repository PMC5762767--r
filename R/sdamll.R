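#' Fit the composed SdaMLL model
#'
#' Two stages: (1) greedy layer-wise pretraining of a stacked denoising
#' autoencoder on the features alone (labels are never visible to this
#' stage), (2) BP-MLL trained online on the encoder codes and the label
#' sets. The encoder is frozen after pretraining; there is no supervised
#' fine-tuning of the stack. With `layer_sizes = d` (no hidden layers) the
#' model degenerates to plain BP-MLL on the raw features, giving the BP-MLL
#' baseline from the same code path.
#'
#' The default architecture is a single code layer of
#' `min(200, ceiling(d / 2))` units — in particular `d -> 200` whenever
#' `d > 400`, compressing a high-dimensional term space to a 200-dimensional
#' code.
#'
#' @param ds A [multilabel_dataset()].
#' @param layer_sizes Integer vector `d, h_1, ..., h_K`; default
#'   `c(d, min(200, ceiling(d/2)))`.
#' @param dae Named list overriding pretraining options (`epochs`,
#'   `learning_rate`, `loss`, `v`); see [pretrain_stack()].
#' @param bpmll Named list overriding classifier options (`M`, `alpha`,
#'   `max_epochs`, `patience`, `tol`); see [train_bpmll()].
#' @param seed Root seed; stage seeds are derived with [stream_seed()].
#' @return Object of class `sdamll_model` holding the frozen
#'   `encoder` ([pretrain_stack()]), the `classifier` ([train_bpmll()]),
#'   and a config snapshot.
#' @export
sdamll_fit <- function(ds, layer_sizes = NULL, dae = list(), bpmll = list(),
                       seed = 1) {
  stopifnot(inherits(ds, "multilabel_dataset"))
  d <- ncol(ds$features)
  if (is.null(layer_sizes)) {
    layer_sizes <- c(d, min(200L, as.integer(ceiling(d / 2))))
  }
  dae_cfg <- modifyList(list(epochs = 10, learning_rate = 0.05,
                             loss = "cross_entropy", v = 0.3), dae)
  bp_cfg <- modifyList(list(M = 32, alpha = 0.05, max_epochs = 50,
                            patience = 3, tol = 1e-9), bpmll)
  encoder <- pretrain_stack(ds$features, layer_sizes,
                            epochs = dae_cfg$epochs,
                            learning_rate = dae_cfg$learning_rate,
                            loss = dae_cfg$loss, v = dae_cfg$v,
                            seed = stream_seed(seed, "pretrain"))
  codes <- sda_transform(encoder, ds$features)
  classifier <- train_bpmll(codes, ds$labels,
                            n_labels = length(ds$label_names),
                            M = bp_cfg$M, alpha = bp_cfg$alpha,
                            max_epochs = bp_cfg$max_epochs,
                            patience = bp_cfg$patience, tol = bp_cfg$tol,
                            seed = stream_seed(seed, "bpmll"))
  structure(list(encoder = encoder, classifier = classifier,
                 label_names = ds$label_names,
                 config = list(layer_sizes = layer_sizes, dae = dae_cfg,
                               bpmll = bp_cfg, seed = seed)),
            class = "sdamll_model")
}

#' Predict pathway scores with a fitted SdaMLL model
#'
#' Encodes the features through the frozen stack (no corruption) and scores
#' them with the trained BP-MLL classifier.
#'
#' @param object A fitted [sdamll_fit()] model.
#' @param newdata Feature matrix or [multilabel_dataset()] with the
#'   encoder's input dimension.
#' @param ... Unused.
#' @return A [ranked_prediction()].
#' @export
predict.sdamll_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "multilabel_dataset")) newdata$features
       else as.matrix(newdata)
  codes <- sda_transform(object$encoder, X)
  predict_scores(object$classifier, codes, label_names = object$label_names)
}

#' @export
print.sdamll_model <- function(x, ...) {
  cat("sdamll_model\n")
  cat("  encoder:", paste(x$encoder$layer_sizes, collapse = " -> "), "\n")
  cat(sprintf("  classifier: %d -> %d -> %d (%d epochs)\n",
              x$classifier$network$d, x$classifier$network$M,
              x$classifier$network$n_labels, x$classifier$epochs_run))
  invisible(x)
}
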