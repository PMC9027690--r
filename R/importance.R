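# Leave-one-feature-out importance: a dense network predicts the blood
# pressure stage from clinical covariates and metabolite features; each
# input is removed in turn and the model retrained on the same split and
# seed schedule. The drop in held-out accuracy is the feature's importance
# (an accuracy increase is a negative importance, permitted by design).

#' Network specification for the stage classifier
#'
#' @param features Ordered character vector of input columns (clinical
#'   covariates and/or metabolite features).
#' @param outcome Outcome column holding integer class codes; default
#'   `"bp_code4"` (four display stages; use `"bp_code5"` for the five-group
#'   coding).
#' @param classes Number of outcome classes (default 4).
#' @param hidden Hidden layer sizes (default `c(32, 16)`).
#' @param epochs,batch_size,learning_rate,momentum Training
#'   hyperparameters of the mini-batch gradient descent.
#' @param split Training fraction of the stratified split, in (0, 1).
#' @return A `net_spec` list.
#' @export
net_spec <- function(features, outcome = "bp_code4", classes = 4L,
                     hidden = c(32L, 16L), epochs = 200L, batch_size = 32L,
                     learning_rate = 0.01, momentum = 0.9, split = 0.8) {
  stopifnot(length(features) >= 1L, length(hidden) >= 1L, classes >= 2L,
            split > 0, split < 1, epochs >= 1L, batch_size >= 1L,
            learning_rate > 0)
  structure(list(features = features, outcome = outcome,
                 classes = as.integer(classes), hidden = as.integer(hidden),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 split = split),
            class = "net_spec")
}

#' Standardize inputs and one-hot encode the outcome
#'
#' Centers and scales each feature using statistics of the *training* rows
#' only (applied unchanged to the held-out rows, so no information leaks
#' from the test split), and expands the class codes into one-hot rows.
#' Zero-variance features (on the training rows) are dropped with a warning.
#'
#' @param data Analysis table.
#' @param spec A [net_spec()].
#' @param train_idx Integer indices of the training rows.
#' @return A list with matrices `x_train`, `x_test`, `y_train`, `y_test`
#'   (one-hot), integer class vectors `class_train`, `class_test`, and the
#'   standardization parameters `center`/`scale`.
#' @export
preprocess <- function(data, spec, train_idx) {
  stopifnot(inherits(spec, "net_spec"))
  missing <- setdiff(c(spec$features, spec$outcome), names(data))
  if (length(missing)) {
    stop("column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(data[, spec$features, drop = FALSE])
  storage.mode(x) <- "double"
  y <- as.integer(data[[spec$outcome]])
  if (anyNA(x) || anyNA(y)) stop("inputs contain missing values",
                                 call. = FALSE)
  if (any(y < 1L | y > spec$classes)) {
    stop("outcome codes must lie in 1..", spec$classes, call. = FALSE)
  }
  center <- colMeans(x[train_idx, , drop = FALSE])
  scale <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
  drop <- scale == 0 | is.na(scale)
  if (any(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(spec$features[drop], collapse = ", "), call. = FALSE)
    x <- x[, !drop, drop = FALSE]
    center <- center[!drop]; scale <- scale[!drop]
    if (ncol(x) == 0L) stop("no features left after dropping zero-variance columns",
                            call. = FALSE)
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, `/`)
  onehot <- function(cls) {
    m <- matrix(0, length(cls), spec$classes)
    m[cbind(seq_along(cls), cls)] <- 1
    m
  }
  test_idx <- setdiff(seq_len(nrow(x)), train_idx)
  list(x_train = xs[train_idx, , drop = FALSE],
       x_test = xs[test_idx, , drop = FALSE],
       y_train = onehot(y[train_idx]), y_test = onehot(y[test_idx]),
       class_train = y[train_idx], class_test = y[test_idx],
       center = center, scale = scale)
}

# stratified train/test split; every class observed in the data must land in
# the training rows
stratified_split <- function(classes, split) {
  idx <- unlist(lapply(unique(classes), function(k) {
    rows <- which(classes == k)
    n_train <- max(1L, round(split * length(rows)))
    if (n_train >= length(rows)) n_train <- length(rows) - 1L
    if (n_train < 1L) {
      stop("stratification error: class ", k,
           " has too few samples to split", call. = FALSE)
    }
    rows[sample.int(length(rows), n_train)]
  }))
  sort(idx)
}

#' Train the blood-pressure stage classifier
#'
#' Stratified 80/20 split (per `spec$split`), training-split
#' standardization, one-hot outcome, dense ReLU network with softmax
#' cross-entropy, mini-batch gradient descent. Fully deterministic given
#' `seed`.
#'
#' @param data Analysis table containing the spec's features and outcome.
#' @param spec A [net_spec()].
#' @param seed Integer seed controlling the split, the weight
#'   initialization and the batch shuffling.
#' @return A `bp_net` with elements `spec`, `params` (weights), `accuracy`
#'   (held-out fraction correct), `n_train`, `n_test`, `seed`.
#' @export
train_classifier <- function(data, spec, seed = 1L) {
  stopifnot(inherits(spec, "net_spec"))
  with_local_seed(seed, {
    y <- as.integer(data[[spec$outcome]])
    if (anyNA(y)) stop("outcome contains missing values", call. = FALSE)
    train_idx <- stratified_split(y, spec$split)
    prep <- preprocess(data, spec, train_idx)
    params <- mlp_train(prep$x_train, prep$y_train, hidden = spec$hidden,
                        epochs = spec$epochs, batch_size = spec$batch_size,
                        learning_rate = spec$learning_rate,
                        momentum = spec$momentum)
    pred <- mlp_predict_class(params, prep$x_test)
    structure(list(spec = spec, params = params,
                   accuracy = mean(pred == prep$class_test),
                   n_train = nrow(prep$x_train),
                   n_test = nrow(prep$x_test),
                   center = prep$center, scale = prep$scale,
                   seed = as.integer(seed)),
              class = "bp_net")
  })
}

#' @export
print.bp_net <- function(x, ...) {
  cat("<bp_net>", length(x$spec$features), "inputs ->",
      paste(x$spec$hidden, collapse = "-"), "->", x$spec$classes,
      "classes\n")
  cat("  held-out accuracy:", sprintf("%.3f", x$accuracy),
      sprintf("(n_train = %d, n_test = %d, seed = %d)\n",
              x$n_train, x$n_test, x$seed))
  invisible(x)
}

#' Predict stage classes for new data
#'
#' @param object A `bp_net`.
#' @param newdata A data frame containing the model's (post-preprocessing)
#'   feature columns.
#' @param ... Unused.
#' @return Integer class predictions.
#' @export
predict.bp_net <- function(object, newdata, ...) {
  feats <- names(object$center)
  x <- as.matrix(newdata[, feats, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  mlp_predict_class(object$params, xs)
}

#' Leave-one-feature-out ablation importance
#'
#' For each feature to test and each seed, retrains the classifier with that
#' input removed -- same split and same seed schedule as the baseline -- and
#' records `delta = baseline accuracy - ablated accuracy`. Positive deltas
#' mean removing the feature hurts (positive importance); negative deltas
#' (accuracy increases on removal) are reported as-is.
#'
#' @param data Analysis table.
#' @param spec Baseline [net_spec()] (all inputs included).
#' @param features_to_test Features to ablate; default all of
#'   `spec$features`.
#' @param seeds Integer vector of seeds to average over (default `1:10`).
#' @return An `importance_report` tibble: `feature_id`, `mean_delta`,
#'   `sd_delta`, `n_seeds`, ordered by decreasing mean delta; baseline
#'   accuracies per seed in `attr(, "baseline")`.
#' @export
ablation_importance <- function(data, spec, features_to_test = spec$features,
                                seeds = 1:10) {
  stopifnot(inherits(spec, "net_spec"))
  if (length(spec$features) < 2L) {
    stop("ablation requires at least two input features", call. = FALSE)
  }
  bad <- setdiff(features_to_test, spec$features)
  if (length(bad)) {
    stop("not inputs of the spec: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  baseline <- vapply(seeds, function(s) {
    train_classifier(data, spec, seed = s)$accuracy
  }, numeric(1))
  deltas <- purrr::map(features_to_test, function(feat) {
    sub <- spec
    sub$features <- setdiff(spec$features, feat)
    abl <- vapply(seeds, function(s) {
      train_classifier(data, sub, seed = s)$accuracy
    }, numeric(1))
    baseline - abl
  })
  out <- tibble::tibble(
    feature_id = features_to_test,
    mean_delta = vapply(deltas, mean, numeric(1)),
    sd_delta = vapply(deltas, stats::sd, numeric(1)),
    n_seeds = length(seeds)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_delta))
  attr(out, "baseline") <- baseline
  class(out) <- c("importance_report", class(out))
  out
}

#' Held-out accuracy as metabolites are added to the covariate model
#'
#' Trains the covariates-only classifier, then adds the ranked metabolites
#' one at a time (conventionally in ascending combined-p order), averaging
#' the held-out accuracy over the seeds at every step.
#'
#' @param data Analysis table.
#' @param covariates Clinical inputs of the baseline model.
#' @param metabolites Ranked metabolite features to add.
#' @param seeds Seeds to average over.
#' @param ... Passed to [net_spec()] (outcome, classes, hidden, epochs, ...).
#' @return A tibble of class `accuracy_curve`: `step` (0 = covariates only),
#'   `feature_added`, `mean_accuracy`, `sd_accuracy`.
#' @export
accuracy_curve <- function(data, covariates, metabolites = character(),
                           seeds = 1:5, ...) {
  steps <- c(list(character(0)),
             lapply(seq_along(metabolites),
                    function(k) metabolites[seq_len(k)]))
  out <- purrr::map2_dfr(steps, c(NA_character_, metabolites),
                         function(mets, added) {
    spec <- net_spec(features = c(covariates, mets), ...)
    acc <- vapply(seeds, function(s) {
      train_classifier(data, spec, seed = s)$accuracy
    }, numeric(1))
    tibble::tibble(step = length(mets), feature_added = added,
                   mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc))
  })
  class(out) <- c("accuracy_curve", class(out))
  out
}
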