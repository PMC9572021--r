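#' Architecture configuration of the 1D-CNN
#'
#' Two fixed variants are supported: variant A stacks three convolutional
#' blocks with 32, 64, and 128 filters; variant B adds a fourth block
#' with 256 filters. Every block is convolution (kernel 1x5, stride 1,
#' "same" padding) -> batch normalization -> ReLU -> max pooling (1x2,
#' stride 1x2). A global average pooling head feeds one fully connected
#' layer with `n_classes` softmax outputs.
#'
#' @param variant `"A"` (3 blocks) or `"B"` (4 blocks).
#' @param n_channels Number of input EEG channels.
#' @param n_classes Number of enrolled subjects (>= 2).
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("A", "B"), n_channels, n_classes) {
  variant <- match.arg(variant)
  if (n_classes < 2) stopf("invalid-config: n_classes must be >= 2")
  if (n_channels < 1) stopf("invalid-config: n_channels must be >= 1")
  structure(
    list(
      variant = variant,
      filters = if (variant == "A") c(32L, 64L, 128L)
                else c(32L, 64L, 128L, 256L),
      kernel = 5L, pool = 2L,
      n_channels = as.integer(n_channels),
      n_classes = as.integer(n_classes)
    ),
    class = "model_config"
  )
}

#' Training configuration
#'
#' Defaults follow the standard recipe for this architecture: Adam with a
#' constant learning rate of 0.001, cross-entropy loss, mini-batches of
#' 64, up to 100 epochs with reshuffling before every epoch, and
#' restoration of the weights from the epoch with the lowest validation
#' loss (first epoch on ties).
#'
#' @param max_epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Constant Adam learning rate.
#' @param seed Integer seed governing weight initialization and epoch
#'   shuffling; training is fully reproducible under it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 100, batch_size = 64,
                         learning_rate = 0.001, seed = 1) {
  if (max_epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stopf("invalid-config: epochs, batch size and learning rate must be positive")
  structure(
    list(max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build an (untrained) 1D-CNN
#'
#' Instantiates the network with He-initialized weights so that the
#' forward pass is immediately usable.
#'
#' @param cfg A [model_config()].
#' @param seed Seed for weight initialization.
#' @return An object of class `eeg_cnn`.
#' @export
build_model <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "model_config"))
  weights <- cnn_init_cpp(cfg$n_channels, cfg$n_classes, cfg$filters,
                          cfg$kernel, as.integer(seed))
  structure(
    list(config = cfg, weights = weights, history = NULL,
         best_epoch = NA_integer_),
    class = "eeg_cnn"
  )
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat(sprintf(
    "<eeg_cnn> variant %s: %d blocks (%s filters), %d channels in, %d classes, %s parameters%s\n",
    x$config$variant, length(x$config$filters),
    paste(x$config$filters, collapse = "/"),
    x$config$n_channels, x$config$n_classes,
    format(n_parameters(x$config), big.mark = ","),
    if (is.null(x$history)) " (untrained)"
    else sprintf(" (trained, best epoch %d)", x$best_epoch)
  ))
  invisible(x)
}

#' Learnable parameter count of a model configuration
#'
#' Closed form: each block contributes `K*(Cin*kernel + 1)` convolution
#' parameters plus `2K` batch-norm scale/shift parameters; the head
#' contributes `n_classes*(K_last + 1)`.
#'
#' @param cfg A [model_config()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(cfg) {
  cin <- cfg$n_channels
  total <- 0
  for (k in cfg$filters) {
    total <- total + k * (cin * cfg$kernel + 1) + 2 * k
    cin <- k
  }
  total + cfg$n_classes * (cin + 1)
}

check_labels <- function(labels, n_classes) {
  if (any(labels < 0 | labels >= n_classes))
    stopf("label error: subject labels must lie in [0, %d)", n_classes)
}

#' Train the 1D-CNN
#'
#' Adam / cross-entropy training with per-epoch reshuffling. After the
#' final epoch the weights are restored to the epoch with minimum
#' validation loss (first occurrence on ties, tracked with strict
#' improvement).
#'
#' @param model An `eeg_cnn` from [build_model()].
#' @param train,val Normalized [segment_set()]s; their subject labels
#'   must lie in `[0, n_classes)`.
#' @param tc A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained `eeg_cnn` with `history` and `best_epoch` filled.
#' @export
train_model <- function(model, train, val, tc = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "eeg_cnn"), inherits(tc, "train_config"))
  if (n_segments(train) == 0 || n_segments(val) == 0)
    stopf("invalid-data: empty training or validation set")
  cfg <- model$config
  if (dim(train$data)[1] != cfg$n_channels)
    stopf("shape error: model expects %d channels, data has %d",
          cfg$n_channels, dim(train$data)[1])
  check_labels(train$subject, cfg$n_classes)
  check_labels(val$subject, cfg$n_classes)
  seeds <- derive_seeds(tc$seed, 2)
  model$weights <- cnn_init_cpp(cfg$n_channels, cfg$n_classes, cfg$filters,
                                cfg$kernel, seeds[1])
  fit <- cnn_train_cpp(model$weights, train$data, train$subject,
                       val$data, val$subject, tc$max_epochs, tc$batch_size,
                       tc$learning_rate, seeds[2], verbose)
  model$weights <- fit$weights
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model
}

#' Predict subject identities for a segment set
#'
#' @param object A trained `eeg_cnn`.
#' @param segments A normalized [segment_set()] with matching channels.
#' @param ... Unused.
#' @return List with `labels` (0-based predicted subject per segment,
#'   argmax of the softmax, ties to the lowest class index) and `probs`
#'   (n x K probability matrix, rows summing to 1).
#' @export
predict.eeg_cnn <- function(object, segments, ...) {
  if (dim(segments$data)[1] != object$config$n_channels)
    stopf("shape error: model expects %d channels, data has %d",
          object$config$n_channels, dim(segments$data)[1])
  probs <- cnn_predict_cpp(object$weights, segments$data, 256L)
  labels <- max.col(probs, ties.method = "first") - 1L
  list(labels = labels, probs = probs)
}
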