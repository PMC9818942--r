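# Compact CNN for six-channel sub-band stacks, plus classical classifiers
# on its pooled features and confusion-matrix metrics.

.CNN_CONV <- data.frame(
  name = c("conv1", "conv2", "conv3", "conv4"),
  cin = c(6, 64, 46, 32), cout = c(64, 46, 32, 16),
  k = c(6, 5, 4, 3), out = c(112, 56, 28, 28))

#' Network specification
#'
#' Describes the compact six-channel classification network: four
#' conv-relu-maxpool blocks (6x6x64/s2, 5x5x46/s2, 4x4x32/s2, 3x3x16/s1;
#' all max pools 2x2 stride 1, extent-preserving), a pooling head, a
#' 16-unit fully connected layer, a 2-unit output layer and the combined
#' softmax-plus-sigmoid activation. With `pooling = "flatten"` (default)
#' the pooling head is an extent-preserving 2x2 stride-1 spatial average
#' whose 28x28x16 output is flattened into the first fully connected
#' layer, giving 316,496 trainable parameters; `pooling = "global"`
#' collapses each channel to its global average (16 features, 116,048
#' parameters).
#'
#' @param pooling `"flatten"` or `"global"`.
#' @return A `network_spec`.
#' @export
network_spec <- function(pooling = c("flatten", "global")) {
  pooling <- match.arg(pooling)
  structure(list(input = c(224, 224, 6), pooling = pooling,
                 conv = .CNN_CONV, fc = c(16, 2)),
            class = "network_spec")
}

#' Per-layer output extents
#'
#' @param spec a `network_spec` (or a `cnn_network`).
#' @return data.frame with `layer`, `height`, `width`, `channels` for
#'   every layer from input to class output.
#' @export
network_shapes <- function(spec = network_spec()) {
  if (inherits(spec, "cnn_network")) spec <- spec$spec
  cv <- spec$conv
  rows <- list(c("input", 224, 224, 6))
  for (i in seq_len(nrow(cv))) {
    o <- cv$out[i]; c <- cv$cout[i]
    rows <- c(rows, list(c(cv$name[i], o, o, c),
                         c(paste0("relu", i), o, o, c),
                         c(paste0("maxpool", i), o, o, c)))
  }
  gap <- if (spec$pooling == "flatten") c("global_avg_pool", 28, 28, 16)
         else c("global_avg_pool", 1, 1, 16)
  rows <- c(rows, list(gap,
                       c("fc1", 1, 1, 16), c("relu5", 1, 1, 16),
                       c("fc2", 1, 1, 2), c("softmax", 1, 1, 2),
                       c("sigmoid", 1, 1, 2), c("class_out", 1, 1, 2)))
  out <- do.call(rbind.data.frame, rows)
  names(out) <- c("layer", "height", "width", "channels")
  out$height <- as.integer(out$height)
  out$width <- as.integer(out$width)
  out$channels <- as.integer(out$channels)
  out
}

# Per-chunk layout of the flat weight vector (matches the C++ backend).
.cnn_layout <- function(pooling) {
  cv <- .CNN_CONV
  fc1_in <- if (pooling == "flatten") 28 * 28 * 16 else 16
  chunks <- list()
  for (i in seq_len(nrow(cv))) {
    fanin <- cv$cin[i] * cv$k[i]^2
    chunks[[paste0(cv$name[i], "_W")]] <- c(n = cv$cout[i] * fanin, fanin = fanin)
    chunks[[paste0(cv$name[i], "_b")]] <- c(n = cv$cout[i], fanin = 0)
  }
  chunks[["fc1_W"]] <- c(n = 16 * fc1_in, fanin = fc1_in)
  chunks[["fc1_b"]] <- c(n = 16, fanin = 0)
  chunks[["fc2_W"]] <- c(n = 2 * 16, fanin = 16)
  chunks[["fc2_b"]] <- c(n = 2, fanin = 0)
  chunks
}

#' Build (initialize) the network
#'
#' Allocates the weight vector with He-normal initialization (biases
#' zero), reproducibly from `seed`.
#'
#' @param spec a `network_spec`.
#' @param seed integer seed.
#' @return A `cnn_network`: list with `spec`, `weights` (flat numeric
#'   vector) and `classes` (filled by [train_cnn()]).
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  set.seed(seed)
  layout <- .cnn_layout(spec$pooling)
  w <- numeric(0)
  for (nm in names(layout)) {
    n <- layout[[nm]]["n"]; fanin <- layout[[nm]]["fanin"]
    w <- c(w, if (fanin > 0) stats::rnorm(n, 0, sqrt(2 / fanin))
              else numeric(n))
  }
  stopifnot(length(w) == .cnn_n_params(spec$pooling == "flatten"))
  structure(list(spec = spec, weights = w, classes = NULL,
                 loss_trace = numeric(0)),
            class = "cnn_network")
}

#' Number of trainable parameters
#'
#' @param x a `cnn_network` or `network_spec`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(x = network_spec()) {
  if (inherits(x, "cnn_network")) x <- x$spec
  .cnn_n_params(x$pooling == "flatten")
}

#' Combined softmax-plus-sigmoid activation
#'
#' For a logit vector \eqn{z}, returns
#' \eqn{\mathrm{softmax}(z)_i + \mathrm{sigmoid}(z_i)} per component.
#' Each component lies in \eqn{(0, 2)}. The softmax term carries the
#' soft class ranking; the added sigmoid breaks exact softmax ties with a
#' componentwise hard decision, which is the rationale for combining the
#' two. The predicted class is the argmax of the combined scores.
#'
#' @param z numeric vector of logits, or a matrix with one logit vector
#'   per row.
#' @return Same shape as `z`.
#' @export
combined_activation <- function(z) {
  if (is.matrix(z)) {
    t(apply(z, 1, combined_activation))
  } else {
    e <- exp(z - max(z))
    e / sum(e) + 1 / (1 + exp(-z))
  }
}

#' Load stacks into the network data store
#'
#' Packs a list of [build_stack()] results (224x224x6 channels each) into
#' the single-precision sample store used by the network backend.
#'
#' @param stacks list of `subband_stack` objects.
#' @return A `stack_data` object with fields `ptr`, `labels` (factor or
#'   `NULL`), `source_ids`, `n`.
#' @export
cnn_stack_data <- function(stacks) {
  if (length(stacks) == 0) stop("empty stack list", call. = FALSE)
  nf <- 224 * 224 * 6
  ptr <- .cnn_data_alloc(length(stacks), nf)
  labels <- character(length(stacks))
  ids <- character(length(stacks))
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    if (!all(dim(s$channels) == c(224, 224, 6))) {
      stop("stack ", i, " is not 224x224x6", call. = FALSE)
    }
    .cnn_data_set(ptr, i, as.numeric(s$channels))
    labels[i] <- if (is.null(s$label)) NA_character_ else s$label
    ids[i] <- if (is.null(s$source_id)) NA_character_ else s$source_id
  }
  labels <- if (all(is.na(labels))) NULL else factor(labels)
  structure(list(ptr = ptr, labels = labels, source_ids = ids,
                 n = length(stacks)),
            class = "stack_data")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam, batch size 60, learning
#' rate 0.01, 4000 iterations, grouped 90/10 split.
#'
#' @param batch_size minibatch size (`>= 1`).
#' @param learning_rate Adam step size.
#' @param iterations optimizer iterations ("cycles").
#' @param test_fraction held-out fraction of source images.
#' @param seed integer seed for initialization and batch sampling.
#' @return A `training_config`.
#' @export
training_config <- function(batch_size = 60, learning_rate = 0.01,
                            iterations = 4000, test_fraction = 0.1,
                            seed = 1) {
  if (batch_size < 1) stop("batch_size must be at least 1", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "training_config")
}

.as_stack_data <- function(data) {
  if (inherits(data, "stack_data")) data else cnn_stack_data(data)
}

#' Train the network
#'
#' Minimizes cross-entropy on the renormalized combined-activation scores
#' with Adam, recording the minibatch loss at every iteration.
#' Deterministic given `config$seed`.
#'
#' @param network a `cnn_network` (weights are the starting point).
#' @param data a `stack_data` or list of labeled `subband_stack`s.
#' @param config a [training_config()].
#' @param indices optional integer subset of samples to train on
#'   (defaults to all).
#' @param verbose print the loss every 50 iterations?
#' @return The trained `cnn_network`, with `classes` (level order:
#'   negative, positive) and `loss_trace` filled in.
#' @export
train_cnn <- function(network, data, config = training_config(),
                      indices = NULL, verbose = FALSE) {
  data <- .as_stack_data(data)
  if (is.null(data$labels)) stop("training data must carry labels", call. = FALSE)
  if (is.null(indices)) indices <- seq_len(data$n)
  if (length(indices) < 1) stop("empty training set", call. = FALSE)
  classes <- levels(data$labels)
  if (length(unique(data$labels[indices])) < 2) {
    stop("training data must contain two classes", call. = FALSE)
  }
  y <- as.integer(data$labels) - 1L  # 0-based
  flatten <- network$spec$pooling == "flatten"
  w <- network$weights
  m <- numeric(length(w)); v <- numeric(length(w))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  trace <- numeric(config$iterations)
  set.seed(config$seed)
  for (it in seq_len(config$iterations)) {
    idx <- indices[sample.int(length(indices),
                              min(config$batch_size, length(indices)))]
    g <- .cnn_grad(data$ptr, as.integer(idx), y[idx], w, flatten)
    m <- b1 * m + (1 - b1) * g$grad
    v <- b2 * v + (1 - b2) * g$grad^2
    mh <- m / (1 - b1^it)
    vh <- v / (1 - b2^it)
    w <- w - lr * mh / (sqrt(vh) + eps)
    trace[it] <- g$loss
    if (verbose && it %% 50 == 0) {
      message(sprintf("iter %d loss %.4f", it, g$loss))
    }
  }
  network$weights <- w
  network$classes <- classes
  network$loss_trace <- trace
  network
}

#' Predict with the network
#'
#' @param object a trained `cnn_network`.
#' @param data a `stack_data` or list of stacks.
#' @param type `"class"` (argmax of the combined activation), `"prob"`
#'   (renormalized combined scores) or `"score"` (raw combined
#'   activation, components in `(0, 2)`).
#' @param indices optional integer subset of samples.
#' @param ... unused.
#' @return Factor of classes, or a numeric matrix.
#' @export
predict.cnn_network <- function(object, data, type = c("class", "prob", "score"),
                                indices = NULL, ...) {
  type <- match.arg(type)
  data <- .as_stack_data(data)
  if (is.null(indices)) indices <- seq_len(data$n)
  fw <- .cnn_forward(data$ptr, as.integer(indices), object$weights,
                     object$spec$pooling == "flatten")
  act <- combined_activation(fw$logits)
  if (type == "score") return(act)
  if (type == "prob") return(act / rowSums(act))
  cls <- if (is.null(object$classes)) c("class0", "class1") else object$classes
  factor(cls[max.col(act, ties.method = "first")], levels = cls)
}

#' Extract pooled network features
#'
#' Returns the 16-length representation of the classifier head for every
#' sample: the activations of the 16-unit fully connected layer fed by
#' the pooling head (`pooling = "flatten"`), or the global-average-pooled
#' channel means themselves (`pooling = "global"`). Computed with frozen
#' weights, so train and test features come from the same map.
#'
#' @param network a (typically trained) `cnn_network`.
#' @param data a `stack_data` or list of stacks.
#' @param indices optional integer subset of samples.
#' @return Numeric matrix, one 16-length row per sample.
#' @export
extract_features <- function(network, data, indices = NULL) {
  data <- .as_stack_data(data)
  if (is.null(indices)) indices <- seq_len(data$n)
  fw <- .cnn_forward(data$ptr, as.integer(indices), network$weights,
                     network$spec$pooling == "flatten")
  fw$features
}

#' Source-grouped train/test split
#'
#' Splits samples by originating source image so that no source (and
#' hence none of its augmented variants) contributes to both sides.
#'
#' @param x a `stack_data`, a list of stacks, or a character vector of
#'   source ids (one per sample).
#' @param test_fraction fraction of source ids held out.
#' @param seed integer seed.
#' @return List with `train` and `test` (integer sample indices) and
#'   `test_ids` (the held-out source ids).
#' @export
grouped_split <- function(x, test_fraction = 0.1, seed = 1) {
  ids <- if (is.character(x)) x
         else if (inherits(x, "stack_data")) x$source_ids
         else vapply(x, function(s) {
           if (is.null(s$source_id)) NA_character_ else s$source_id
         }, character(1))
  if (anyNA(ids)) stop("every sample needs a source_id", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  uid <- unique(ids)
  n_test <- max(1L, round(test_fraction * length(uid)))
  set.seed(seed)
  test_ids <- sample(uid, n_test)
  test <- which(ids %in% test_ids)
  list(train = setdiff(seq_along(ids), test), test = test,
       test_ids = test_ids)
}

#' Translational augmentation
#'
#' Generates shifted copies of an image with integer per-axis shifts
#' drawn uniformly from \eqn{\pm\{1, \dots, max\_shift\}} (each axis
#' shift is nonzero, so no variant equals the original position). Border
#' rows/columns are replicated. No rotation or scaling is applied, which
#' preserves size- and orientation-dependent features.
#'
#' @param image numeric matrix.
#' @param n_variants number of shifted copies.
#' @param max_shift largest shift magnitude in pixels (default 11).
#' @param seed integer seed.
#' @return List of `n_variants` matrices; each carries attributes `shift`.
#' @export
augment_translate <- function(image, n_variants, max_shift = 11, seed = 1) {
  if (max_shift < 1) stop("max_shift must be at least 1", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_variants), function(i) {
    s <- sample(c(-(max_shift:1), 1:max_shift), 2, replace = TRUE)
    out <- .shift_replicate(image, s[1], s[2])
    attr(out, "shift") <- s
    out
  })
}

.shift_replicate <- function(x, dy, dx) {
  n1 <- nrow(x); n2 <- ncol(x)
  i <- pmin(pmax(seq_len(n1) - dy, 1), n1)
  j <- pmin(pmax(seq_len(n2) - dx, 1), n2)
  x[i, j]
}

#' Classical classifiers on network features
#'
#' Trains a support vector machine, k-nearest-neighbour (k = 1) or random
#' forest classifier with its implementation defaults on feature vectors
#' (typically the pooled network features).
#'
#' @param features numeric matrix, one row per sample.
#' @param labels factor or character class labels.
#' @param kind `"svm"`, `"knn"` or `"random_forest"`.
#' @param seed integer seed (random forest and any tie-breaking).
#' @return A `cwriig_classifier`.
#' @export
fit_classical <- function(features, labels, kind = c("svm", "knn", "random_forest"),
                          seed = 1) {
  kind <- match.arg(kind)
  labels <- factor(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels are not aligned", call. = FALSE)
  }
  set.seed(seed)
  model <- switch(kind,
    svm = e1071::svm(x = features, y = labels),
    knn = list(x = features, y = labels, k = 1L),
    random_forest = randomForest::randomForest(x = features, y = labels))
  structure(list(kind = kind, model = model, classes = levels(labels)),
            class = "cwriig_classifier")
}

#' @export
predict.cwriig_classifier <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  switch(object$kind,
    svm = stats::predict(object$model, features),
    knn = class::knn(object$model$x, features, object$model$y,
                     k = object$model$k),
    random_forest = stats::predict(object$model, features))
}

#' Confusion-matrix metrics
#'
#' Computes the confusion matrix and derived rates with the malignant
#' class as positive: accuracy, sensitivity (recall on malignant),
#' specificity (recall on benign), positive and negative predictive
#' value, and F1. Rates with an empty denominator are reported as `NA`
#' (undefined), never as an error.
#'
#' @param truth,pred factors or characters of true and predicted labels.
#' @param positive the positive-class label (default `"malignant"`).
#' @return A `cwriig_metrics` list with `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `f1`.
#' @export
classification_metrics <- function(truth, pred, positive = "malignant") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); ppv <- div(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (ppv + sens) == 0) NA_real_
        else 2 * ppv * sens / (ppv + sens)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = div(tp + tn, tp + tn + fp + fn),
                 sensitivity = sens, specificity = div(tn, tn + fp),
                 ppv = ppv, npv = div(tn, tn + fn), f1 = f1,
                 positive = positive),
            class = "cwriig_metrics")
}

#' @export
print.cwriig_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d (positive = %s)\n",
              x$tp, x$tn, x$fp, x$fn, x$positive))
  for (f in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1")) {
    cat(sprintf("  %-12s %s\n", f,
                ifelse(is.na(x[[f]]), "undefined", sprintf("%.4f", x[[f]]))))
  }
  invisible(x)
}
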