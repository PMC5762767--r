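#' Write a feature matrix
#'
#' TSV: header row of feature names with a leading `instance_id` column;
#' numbers printed with 9 significant digits so write/read round-trips are
#' byte-stable. MTX: MatrixMarket sparse format via the Matrix package, with
#' instance ids and feature names in `<path>.rows` / `<path>.cols` sidecar
#' files (MatrixMarket itself carries no dimnames).
#'
#' @param X Numeric matrix.
#' @param path Output file.
#' @param format `"tsv"` or `"mtx"`; default guessed from the extension.
#' @param feature_names,instance_ids Optional names; default from dimnames.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path, format = NULL, feature_names = NULL,
                           instance_ids = NULL) {
  X <- as.matrix(X)
  format <- format %||% (if (grepl("\\.mtx$", path)) "mtx" else "tsv")
  feature_names <- feature_names %||% colnames(X) %||%
    sprintf("t%04d", seq_len(ncol(X)))
  instance_ids <- instance_ids %||% rownames(X) %||%
    sprintf("g%04d", seq_len(nrow(X)))
  if (format == "tsv") {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("instance_id", feature_names), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(X)), function(i) {
      paste(c(instance_ids[i], format_num(X[i, ])), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  } else if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(instance_ids, paste0(path, ".rows"))
    writeLines(feature_names, paste0(path, ".cols"))
  } else {
    stop("unknown feature format: ", format)
  }
  invisible(path)
}

#' Read a feature matrix
#'
#' Counterpart of [write_features()]. Values are validated into `[0, 1]`;
#' an out-of-range value is an error naming the offending cell unless
#' `rescale = TRUE`, in which case non-negative values are rescaled
#' column-wise with a warning.
#'
#' @param path TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`; default guessed from the extension.
#' @param rescale Rescale out-of-range (non-negative) values instead of
#'   failing.
#' @return Numeric matrix with instance ids as rownames and feature names
#'   as colnames.
#' @export
read_features <- function(path, format = NULL, rescale = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% (if (grepl("\\.mtx$", path)) "mtx" else "tsv")
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE, encoding = "UTF-8")
    if (ncol(df) < 2L || names(df)[1] != "instance_id") {
      stop("malformed feature TSV '", path,
           "': expected a header starting with 'instance_id'")
    }
    X <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(X) <- "double"
    rownames(X) <- as.character(df[[1]])
  } else if (format == "mtx") {
    X <- as.matrix(Matrix::readMM(path))
    rfile <- paste0(path, ".rows"); cfile <- paste0(path, ".cols")
    if (file.exists(rfile)) rownames(X) <- readLines(rfile)
    else rownames(X) <- sprintf("g%04d", seq_len(nrow(X)))
    if (file.exists(cfile)) colnames(X) <- readLines(cfile)
    else colnames(X) <- sprintf("t%04d", seq_len(ncol(X)))
  } else {
    stop("unknown feature format: ", format)
  }
  if (anyNA(X)) stop("malformed feature file '", path, "': missing values")
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    # negative term frequencies are nonsense regardless of rescaling
    stop(sprintf(
      "negative feature value at instance '%s', feature '%s': %g",
      rownames(X)[neg[1, 1]], colnames(X)[neg[1, 2]],
      X[neg[1, 1], neg[1, 2]]))
  }
  bad <- which(X > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    if (!rescale) {
      stop(sprintf(
        "feature value out of [0,1] at instance '%s', feature '%s': %g %s",
        rownames(X)[bad[1, 1]], colnames(X)[bad[1, 2]],
        X[bad[1, 1], bad[1, 2]],
        "(use rescale = TRUE / --rescale to rescale column-wise)"))
    }
    warning("rescaling feature columns into [0, 1]")
    X <- rescale_features(X)
  }
  X
}

#' Write label assignments
#'
#' TSV with header `instance_id<TAB>labels`, the labels of each instance as
#' a comma-separated list of label *names*.
#'
#' @param labels List of integer index vectors or character vectors.
#' @param label_names The label universe (used to turn indices into names).
#' @param instance_ids Character ids, same length as `labels`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, label_names, instance_ids, path) {
  lines <- vapply(seq_along(labels), function(i) {
    y <- labels[[i]]
    nm <- if (is.character(y)) y else label_names[y]
    paste(instance_ids[i], paste(nm, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c("instance_id\tlabels", lines), path, useBytes = FALSE)
  invisible(path)
}

#' Read label assignments
#'
#' Counterpart of [write_labels()]. The label universe is the sorted set of
#' distinct label names in the file. Duplicate instance ids and empty label
#' cells are errors; when `instance_ids` is supplied (from the feature
#' matrix), any mismatch between the two id sets is an error naming the id.
#'
#' @param path Label TSV.
#' @param instance_ids Optional feature-matrix ids to join against; labels
#'   are returned in this order.
#' @return List with `labels` (list of integer index vectors),
#'   `label_names`, `instance_ids`.
#' @export
read_labels <- function(path, instance_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, encoding = "UTF-8",
                   colClasses = "character")
  if (ncol(df) != 2L || !identical(names(df), c("instance_id", "labels"))) {
    stop("malformed label TSV '", path,
         "': expected columns instance_id, labels")
  }
  ids <- df$instance_id
  if (anyDuplicated(ids)) {
    stop("duplicate instance id in '", path, "': ",
         ids[duplicated(ids)][1])
  }
  if (any(!nzchar(trimws(df$labels)))) {
    stop("empty label cell at instance '",
         ids[which(!nzchar(trimws(df$labels)))[1]], "'")
  }
  sets <- strsplit(df$labels, ",", fixed = TRUE)
  sets <- lapply(sets, trimws)
  universe <- sort(unique(unlist(sets)))
  labels <- lapply(sets, function(s) sort(match(s, universe)))
  if (!is.null(instance_ids)) {
    missing_in_feat <- setdiff(ids, instance_ids)
    if (length(missing_in_feat)) {
      stop("instance '", missing_in_feat[1],
           "' present in labels but not in features")
    }
    missing_in_lab <- setdiff(instance_ids, ids)
    if (length(missing_in_lab)) {
      stop("instance '", missing_in_lab[1],
           "' present in features but not in labels")
    }
    labels <- labels[match(instance_ids, ids)]
    ids <- instance_ids
  }
  list(labels = labels, label_names = universe, instance_ids = ids)
}

#' Read a full dataset from feature + label files
#'
#' @param features_path Feature TSV/MTX (see [read_features()]).
#' @param labels_path Label TSV (see [read_labels()]).
#' @param rescale Passed to [read_features()].
#' @return A validated [multilabel_dataset()].
#' @export
read_dataset <- function(features_path, labels_path, rescale = FALSE) {
  X <- read_features(features_path, rescale = rescale)
  lab <- read_labels(labels_path, instance_ids = rownames(X))
  multilabel_dataset(X, lab$labels, label_names = lab$label_names,
                     feature_names = colnames(X),
                     instance_ids = rownames(X))
}

#' Write a dataset to feature + label files
#'
#' @param ds A [multilabel_dataset()].
#' @param features_path,labels_path Output paths.
#' @param format Feature format, `"tsv"` or `"mtx"` (default from
#'   extension).
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(ds, features_path, labels_path, format = NULL) {
  write_features(ds$features, features_path, format = format,
                 feature_names = ds$feature_names,
                 instance_ids = ds$instance_ids)
  write_labels(ds$labels, ds$label_names, ds$instance_ids, labels_path)
  invisible(c(features_path, labels_path))
}

# ---- model serialization: numeric-array TSVs + JSON manifest -------------

write_array <- function(x, path) {
  x <- as.matrix(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(vapply(seq_len(nrow(x)), function(i) {
    paste(sprintf("%.17g", x[i, ]), collapse = "\t")
  }, character(1)), con)
  invisible(path)
}

read_array <- function(path) {
  as.matrix(read.table(path, header = FALSE, sep = "\t",
                       colClasses = "numeric"))
}

#' Save a fitted model as a text archive
#'
#' Writes every numeric array (encoder layer weights/biases, classifier
#' weights) as a plain TSV plus a `model.json` manifest describing layer sizes,
#' loss kind, seeds and file layout — a library-agnostic on-disk format.
#'
#' @param model A fitted [sdamll_fit()] model.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "sdamll_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(model$encoder$layers)) {
    p <- model$encoder$layers[[k]]
    write_array(p$W, file.path(dir, sprintf("enc%d_W.tsv", k)))
    write_array(p$b, file.path(dir, sprintf("enc%d_b.tsv", k)))
    write_array(p$b_prime, file.path(dir, sprintf("enc%d_bprime.tsv", k)))
  }
  net <- model$classifier$network
  write_array(net$V, file.path(dir, "clf_V.tsv"))
  write_array(net$W, file.path(dir, "clf_W.tsv"))
  write_array(net$gamma, file.path(dir, "clf_gamma.tsv"))
  write_array(net$theta, file.path(dir, "clf_theta.tsv"))
  write_array(model$classifier$trace, file.path(dir, "clf_trace.tsv"))
  manifest <- list(
    format = "sdamll-model/1",
    layer_sizes = model$encoder$layer_sizes,
    label_names = model$label_names,
    dae = model$encoder$config,
    bpmll = model$classifier$config,
    config = model$config,
    files = list(encoder = sprintf("enc%d_{W,b,bprime}.tsv",
                                   seq_along(model$encoder$layers)),
                 classifier = c("clf_V.tsv", "clf_W.tsv", "clf_gamma.tsv",
                                "clf_theta.tsv")))
  jsonlite::write_json(manifest, file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model saved with [save_model()]
#'
#' @param dir Model directory.
#' @return An `sdamll_model`.
#' @export
load_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  sizes <- as.integer(man$layer_sizes)
  layers <- list()
  for (k in seq_len(length(sizes) - 1L)) {
    layers[[k]] <- dae_params(
      d = sizes[k], d_prime = sizes[k + 1L],
      W = read_array(file.path(dir, sprintf("enc%d_W.tsv", k))),
      b = drop(read_array(file.path(dir, sprintf("enc%d_b.tsv", k)))),
      b_prime = drop(read_array(file.path(dir,
                                          sprintf("enc%d_bprime.tsv", k)))))
  }
  encoder <- structure(list(layers = layers, layer_sizes = sizes,
                            traces = NULL, config = man$dae),
                       class = "stacked_encoder")
  V <- read_array(file.path(dir, "clf_V.tsv"))
  W <- read_array(file.path(dir, "clf_W.tsv"))
  net <- structure(list(V = V, W = W,
                        gamma = drop(read_array(file.path(dir,
                                                          "clf_gamma.tsv"))),
                        theta = drop(read_array(file.path(dir,
                                                          "clf_theta.tsv"))),
                        d = nrow(V), M = ncol(V), n_labels = ncol(W)),
                   class = "bpmll_network")
  classifier <- structure(
    list(network = net,
         trace = drop(read_array(file.path(dir, "clf_trace.tsv"))),
         epochs_run = NA_integer_, skipped = NA_integer_,
         config = man$bpmll),
    class = "bpmll")
  structure(list(encoder = encoder, classifier = classifier,
                 label_names = man$label_names, config = man$config),
            class = "sdamll_model")
}

#' Write ranked scores as TSV
#'
#' `instance_id` plus one column per label.
#'
#' @param rp A [ranked_prediction()].
#' @param instance_ids Instance ids, one per row.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_scores <- function(rp, instance_ids, path) {
  S <- resolve_pred(rp)
  nm <- colnames(S) %||% sprintf("L%02d", seq_len(ncol(S)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("instance_id", nm), collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(S)), function(i) {
    paste(c(instance_ids[i], format_num(S[i, ])), collapse = "\t")
  }, character(1)), con)
  invisible(path)
}

#' Read scores written by [write_scores()]
#'
#' @param path Score TSV.
#' @return A [ranked_prediction()] with instance ids as rownames.
#' @export
read_scores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  ranked_prediction(S)
}

# Manifest written beside every CLI output: config, seeds, input digests,
# package version. No timestamps, so reruns are byte-identical.
write_manifest <- function(dir, command, config, inputs = character()) {
  digests <- if (length(inputs)) {
    stats::setNames(as.character(tools::md5sum(inputs)), basename(inputs))
  } else NULL
  jsonlite::write_json(
    list(tool = "sdamll",
         version = as.character(utils::packageVersion("sdamll")),
         command = command, config = config, input_md5 = digests),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
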