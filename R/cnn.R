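# Subject-identification CNN: configuration, cross-validation plan, and the
# train/evaluate loop (backed by the compiled single-precision engine).

#' CNN configuration
#'
#' The default stack: three 3x3 valid convolutions with 32 filters, each
#' followed by 2x2 max pooling, then dense-128 (ReLU) and a softmax output.
#' With 134 x 134 x 3 input the feature-map widths are 132, 66, 64, 32, 30,
#' 15 and the flattened size is 7200.
#'
#' @param input_shape image dimensions (height, width, channels).
#' @param n_classes number of subjects.
#' @param filters convolution filters per layer.
#' @param kernel convolution kernel side (valid padding).
#' @param dense units in the penultimate fully-connected layer.
#' @param learning_rate,epochs,batch_size Adam training settings.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(input_shape = c(134, 134, 3), n_classes = 7,
                       filters = 32, kernel = 3, dense = 128,
                       learning_rate = 0.001, epochs = 10, batch_size = 32) {
  structure(list(input_shape = input_shape, n_classes = n_classes,
                 filters = filters, kernel = kernel, dense = dense,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size),
            class = "cnn_config")
}

#' Build the CNN and tabulate its layers
#'
#' Computes output shapes and per-layer trainable parameter counts for the
#' configured stack.  The spatial input must be 134 x 134 x 3, the shape the
#' architecture is specified for.
#'
#' @param cfg a `cnn_config`.
#' @return a `carotid_cnn`: list with `config` and `layers`, a data.frame of
#'   layer type, output shape and parameter count.
#' @export
build_model <- function(cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  if (!identical(as.integer(cfg$input_shape), c(134L, 134L, 3L)))
    stop("input shape must be 134x134x3")
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]; c0 <- cfg$input_shape[3]
  k <- cfg$kernel; f <- cfg$filters
  shapes <- list(); params <- c(); types <- c()
  add <- function(type, shape, p) {
    types[[length(types) + 1]] <<- type
    shapes[[length(shapes) + 1]] <<- shape
    params[[length(params) + 1]] <<- p
  }
  add("Image input", c(h, w, c0), 0)
  chans <- c0
  for (i in 1:3) {
    h <- h - k + 1; w <- w - k + 1
    add("Convolution", c(h, w, f), (k * k * chans) * f + f)
    chans <- f
    if (h %% 2 != 0 && i < 3) stop("feature map not divisible for pooling")
    h <- h %/% 2; w <- w %/% 2
    add("Max-pooling", c(h, w, f), 0)
  }
  flat <- h * w * f
  add("Fully connected", cfg$dense, flat * cfg$dense + cfg$dense)
  add("Fully connected", cfg$n_classes,
      cfg$dense * cfg$n_classes + cfg$n_classes)
  layers <- data.frame(
    layer = seq_along(types),
    type = unlist(types),
    output_shape = vapply(shapes, function(s) paste(s, collapse = "x"), ""),
    parameters = unlist(params))
  structure(list(config = cfg, layers = layers, flat_size = flat),
            class = "carotid_cnn")
}

#' @export
print.carotid_cnn <- function(x, ...) {
  cat("Small CNN\n")
  print(x$layers, row.names = FALSE)
  cat(sprintf("Total parameters: %d\n", sum(x$layers$parameters)))
  invisible(x)
}

#' Stratified repeated k-fold cross-validation splits
#'
#' Each repetition independently shuffles and partitions every class into
#' `k` folds whose class counts differ by at most one sample, yielding
#' `k * repetitions` train/test splits.
#'
#' @param labels class label vector (coerced to factor).
#' @param k folds per repetition.
#' @param repetitions number of repetitions.
#' @param seed integer seed; splits are a pure function of it.
#' @return list of `k * repetitions` lists with `train`, `test`,
#'   `repetition`, `fold` (indices into `labels`).
#' @export
make_cv_splits <- function(labels, k = 5, repetitions = 10, seed = 1) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("class(es) with fewer than k samples: ",
         paste(names(tab)[tab < k], collapse = ", "))
  splits <- list()
  for (r in seq_len(repetitions)) {
    fold_of <- integer(length(labels))
    with_seed(derive_seed(seed, r), {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    for (f in seq_len(k)) {
      splits[[length(splits) + 1L]] <- list(
        train = which(fold_of != f), test = which(fold_of == f),
        repetition = r, fold = f)
    }
  }
  splits
}

#' Train and evaluate the CNN over cross-validation splits
#'
#' For each split a fresh model is initialized and trained for the
#' configured number of epochs with Adam on the categorical cross-entropy;
#' the confusion matrix on the held-out fold is returned.  Pixel values
#' must already be scaled to \[0, 1\].
#'
#' @param images list of H x W x 3 arrays in \[0, 1\], or the matrix
#'   produced internally (`D x n`, attribute `img_dim`).
#' @param labels class labels, one per image.
#' @param splits output of [make_cv_splits()].
#' @param cfg a `cnn_config`.
#' @param seed integer seed controlling weight initialization and batch
#'   order (a distinct stream per split).
#' @return list of confusion matrices (true class in rows), one per split.
#' @export
train_and_eval <- function(images, labels, splits, cfg = cnn_config(),
                           seed = 1) {
  if (is.list(images)) images <- images_to_matrix(images)
  d <- attr(images, "img_dim")
  if (is.null(d)) stop("images must carry their dimensions")
  rng <- range(images)
  if (rng[1] < 0 || rng[2] > 1)
    stop("pixel values must be scaled to [0, 1]")
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  if (nlevels(labels) != cfg$n_classes)
    stop("config expects ", cfg$n_classes, " classes, got ", nlevels(labels))
  y <- as.integer(labels) - 1L
  lapply(seq_along(splits), function(s) {
    sp <- splits[[s]]
    cm <- cnn_train_eval_cpp(images, y, sp$train - 1L, sp$test - 1L,
                             cfg$n_classes, d[1], d[2], d[3], cfg$filters,
                             cfg$dense, cfg$learning_rate, cfg$epochs,
                             cfg$batch_size, derive_seed(seed, 1000 + s))
    dimnames(cm) <- list(truth = levels(labels), predicted = levels(labels))
    cm
  })
}

#' Mean multiclass accuracy over confusion matrices
#'
#' @param cms list of square confusion matrices.
#' @return mean of trace/total over the runs.
#' @export
cv_mean_accuracy <- function(cms) {
  mean(vapply(cms, function(cm) sum(diag(cm)) / sum(cm), 0))
}
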