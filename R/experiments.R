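#' Seeded k-fold split
#'
#' Randomly partitions `1..m` into `k` disjoint, exhaustive folds whose
#' sizes differ by at most one, via a seeded shuffle. Plain random (not
#' label-stratified) by default; see [run_comparison()] for a stratified
#' option.
#'
#' @param m Number of instances.
#' @param k Number of folds (`k <= m`).
#' @param seed Integer seed.
#' @return List of `k` integer index vectors (the validation fold indices).
#' @export
kfold_split <- function(m, k, seed = 1) {
  if (k > m) stop("k must not exceed m")
  if (k < 2) stop("k must be >= 2")
  withr::with_seed(seed, {
    idx <- sample.int(m)
    sizes <- rep(m %/% k, k)
    if (m %% k) sizes[seq_len(m %% k)] <- sizes[seq_len(m %% k)] + 1L
    split(idx, rep(seq_len(k), times = sizes))
  })
}

builtin_method <- function(name, args = list()) {
  switch(
    name,
    sdamll = function(train, X, seed) {
      model <- do.call(sdamll_fit, c(list(ds = train, seed = seed),
                                     args[["sdamll"]] %||% list()))
      predict(model, X)
    },
    bpmll = function(train, X, seed) {
      # empty-stack path: BP-MLL on the raw features
      model <- do.call(sdamll_fit, c(
        list(ds = train, layer_sizes = ncol(train$features), seed = seed),
        args[["bpmll"]] %||% list()))
      predict(model, X)
    },
    knn = function(train, X, seed) {
      do.call(knn_scores, c(list(train = train, X = X),
                            args[["knn"]] %||% list()))
    },
    dt = function(train, X, seed) {
      do.call(dt_scores, c(list(train = train, X = X),
                           args[["dt"]] %||% list()))
    },
    stop("unknown method: ", name)
  )
}

#' k-fold cross-validated method comparison
#'
#' For each fold, fits each method on the training split only, scores the
#' validation split, and computes the three ranking metrics; results are
#' aggregated as mean and standard deviation over folds. Methods may be
#' built-in names (`"sdamll"`, `"bpmll"` — the empty-stack BP-MLL-on-raw-
#' features path —, `"knn"`, `"dt"`) or functions
#' `function(train_ds, X_valid, seed) -> ranked_prediction`. A method
#' failure on a fold is recorded, the fold is marked invalid for that
#' method, and the run continues. Instances whose label set is the full
#' universe are excluded from validation scoring (the metrics reject them).
#'
#' @param ds A [multilabel_dataset()].
#' @param methods Character vector of built-in names and/or a named list of
#'   method functions.
#' @param k Number of folds (default 10).
#' @param seed Root seed (fold assignment and per-fold method seeds).
#' @param method_args Named list of per-method argument lists for the
#'   built-ins, e.g. `list(knn = list(k = 5))`.
#' @return Object of class `cv_result`: `summary` (method x metric mean/sd
#'   data frame), `per_fold` (long data frame), `folds`, `pooled` (per
#'   method, held-out scores for every instance, each scored by the model
#'   trained without it), `errors`, and the config.
#' @export
run_comparison <- function(ds, methods = c("sdamll", "bpmll", "knn", "dt"),
                           k = 10, seed = 1, method_args = list()) {
  stopifnot(inherits(ds, "multilabel_dataset"))
  if (is.character(methods)) {
    methods <- stats::setNames(
      lapply(methods, builtin_method, args = method_args), methods)
  }
  m <- nrow(ds$features)
  n <- length(ds$label_names)
  folds <- kfold_split(m, k, seed = stream_seed(seed, "folds"))
  per_fold <- list()
  errors <- list()
  pooled <- lapply(methods, function(.) matrix(NA_real_, m, n))
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    tr <- setdiff(seq_len(m), val)
    train_ds <- subset_dataset(ds, tr)
    Xv <- ds$features[val, , drop = FALSE]
    ok_val <- val[lengths(ds$labels[val]) < n]   # metrics need proper Y
    for (nm in names(methods)) {
      res <- tryCatch({
        rp <- methods[[nm]](train_ds, Xv, stream_seed(seed, paste0(nm, f)))
        S <- resolve_pred(rp)
        pooled[[nm]][val, ] <- S
        rep_ok <- evaluate_ranking(S[match(ok_val, val), , drop = FALSE],
                                   ds$labels[ok_val])
        data.frame(fold = f, method = nm,
                   average_precision = rep_ok$average_precision,
                   ranking_loss = rep_ok$ranking_loss,
                   coverage = rep_ok$coverage, m = rep_ok$m)
      }, error = function(e) {
        errors[[length(errors) + 1L]] <<- list(fold = f, method = nm,
                                               message = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) per_fold[[length(per_fold) + 1L]] <- res
    }
  }
  per_fold <- do.call(rbind, per_fold)
  summ <- do.call(rbind, lapply(names(methods), function(nm) {
    sub <- if (is.null(per_fold)) {
      data.frame()
    } else {
      per_fold[per_fold$method == nm, , drop = FALSE]
    }
    if (!nrow(sub)) {
      return(data.frame(method = nm, average_precision = NA_real_,
                        ranking_loss = NA_real_, coverage = NA_real_,
                        sd_average_precision = NA_real_,
                        sd_ranking_loss = NA_real_, sd_coverage = NA_real_,
                        folds = 0L))
    }
    data.frame(method = nm,
               average_precision = mean(sub$average_precision),
               ranking_loss = mean(sub$ranking_loss),
               coverage = mean(sub$coverage),
               sd_average_precision = sd(sub$average_precision),
               sd_ranking_loss = sd(sub$ranking_loss),
               sd_coverage = sd(sub$coverage),
               folds = nrow(sub))
  }))
  structure(list(summary = summ, per_fold = per_fold, folds = folds,
                 pooled = lapply(pooled, ranked_prediction,
                                 label_names = ds$label_names),
                 errors = errors,
                 config = list(k = k, seed = seed,
                               methods = names(methods))),
            class = "cv_result")
}

subset_dataset <- function(ds, idx) {
  multilabel_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                     label_names = ds$label_names,
                     feature_names = ds$feature_names,
                     instance_ids = ds$instance_ids[idx], validate = FALSE)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$config$k,
              x$config$seed))
  grid <- x$summary[, c("method", "average_precision", "ranking_loss",
                        "coverage")]
  grid[-1] <- lapply(grid[-1], round, 3)
  print(grid, row.names = FALSE)
  if (length(x$errors)) cat(length(x$errors), "method/fold failure(s)\n")
  invisible(x)
}

#' Permutation null of a dataset statistic
#'
#' Recomputes `statistic` with the label sets randomly permuted across
#' instances `n_perm` times — the "no better than chance" reference for any
#' label-dependent performance statistic (feature rows are untouched, so
#' the marginal label-set distribution is preserved exactly).
#'
#' @param ds A [multilabel_dataset()].
#' @param statistic Function taking a `multilabel_dataset` and returning a
#'   scalar.
#' @param n_perm Number of permutations (`>= 100` recommended).
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `quantiles` (2.5/25/50/75/97.5%), and
#'   the full vector of `values`.
#' @export
permutation_null <- function(ds, statistic, n_perm = 200, seed = 1) {
  stopifnot(inherits(ds, "multilabel_dataset"), n_perm >= 1)
  m <- nrow(ds$features)
  values <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(m)
      ds_b <- ds
      ds_b$labels <- ds$labels[perm]
      statistic(ds_b)
    }, numeric(1))
  })
  list(mean = mean(values), sd = sd(values),
       quantiles = quantile(values, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       values = values)
}
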