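#' Network architecture and training configuration
#'
#' Defaults follow the architecture used for scenario discrimination on
#' SNP images: three 1-D convolutions along the locus axis with kernel 3
#' and no bias (125, 250, 250 filters), each intercalated with batch
#' normalization and ReLU, one max-pooling step (window 2) after the
#' convolutional stack, then two dense layers of 125 units with 50\%
#' dropout, and a 3-class softmax output. Training uses SGD (learning
#' rate 0.01, momentum 0.9) on categorical cross-entropy in minibatches
#' of 500, keeps the weights of the best validation-accuracy epoch
#' (model checkpoint), and stops early after `patience_epochs` epochs
#' without validation improvement.
#'
#' @param n_loci Image height (SNPs per image).
#' @param n_samples Image width (haplotype columns = input channels).
#' @param conv_filters Filters of the three convolutional layers.
#' @param kernel Convolution kernel size.
#' @param pool Max-pooling window.
#' @param dense_units Units of the two dense layers.
#' @param dropout Dropout probability after each dense layer.
#' @param classes Number of output classes.
#' @param batch_size SGD minibatch size.
#' @param patience_epochs Early-stopping patience.
#' @param max_epochs Hard epoch ceiling.
#' @param learning_rate,momentum SGD hyperparameters.
#' @param bn_momentum Running-statistics momentum of batch normalization.
#' @return A `network_config` list.
#' @export
network_config <- function(n_loci, n_samples,
                           conv_filters = c(125L, 250L, 250L),
                           kernel = 3L, pool = 2L,
                           dense_units = c(125L, 125L),
                           dropout = 0.5, classes = 3L,
                           batch_size = 500L, patience_epochs = 150L,
                           max_epochs = 1000L, learning_rate = 0.01,
                           momentum = 0.9, bn_momentum = 0.9) {
  stopifnot(n_loci > 0, n_samples > 0, all(conv_filters > 0),
            all(dense_units > 0), classes >= 2, kernel >= 1, pool >= 1,
            batch_size > 0, patience_epochs > 0, max_epochs > 0)
  if (n_loci < 3 * (kernel - 1) + pool)
    abort("`n_loci` is too small for three convolutions plus pooling")
  structure(list(
    n_loci = as.integer(n_loci), n_samples = as.integer(n_samples),
    conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
    pool = as.integer(pool), dense_units = as.integer(dense_units),
    dropout = dropout, classes = as.integer(classes),
    batch_size = as.integer(batch_size),
    patience_epochs = as.integer(patience_epochs),
    max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
    momentum = momentum, bn_momentum = bn_momentum
  ), class = "network_config")
}

#' Build an untrained scenario classifier
#'
#' Initializes the convolutional network's weights (He-scaled normal
#' draws from R's RNG, so two builds under the same seed are identical).
#'
#' @param n_loci,n_samples Input image shape.
#' @param config A [network_config()]; built from the shape if omitted.
#' @param seed Optional integer seed for the weight initialization.
#' @param class_labels Labels reported by [predict.cnn_classifier()];
#'   defaults to [scenarios()].
#' @return An object of class `cnn_classifier` (untrained, temperature 1).
#' @export
build_network <- function(n_loci, n_samples, config = NULL, seed = NULL,
                          class_labels = scenarios()) {
  if (is.null(config)) config <- network_config(n_loci, n_samples)
  stopifnot(inherits(config, "network_config"),
            length(class_labels) == config$classes)
  if (!is.null(seed)) set.seed(seed)
  params <- cnn_init_cpp(config)
  structure(list(
    params = params, config = config, class_labels = class_labels,
    temperature = 1, history = NULL, best_epoch = NA_integer_,
    trained = FALSE
  ), class = "cnn_classifier")
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cfg <- x$config
  cat("<cnn_classifier>", cfg$n_loci, "x", cfg$n_samples, "->",
      paste(cfg$conv_filters, collapse = "/"), "conv |",
      paste(cfg$dense_units, collapse = "/"), "dense |",
      cfg$classes, "classes\n")
  if (x$trained) {
    cat(sprintf("  trained: best epoch %d, val accuracy %.4f; T = %.3f\n",
                x$best_epoch, max(x$history$val_accuracy), x$temperature))
  } else cat("  untrained\n")
  invisible(x)
}

batch_labels_int <- function(batch, model, idx) {
  y <- match(batch$labels[idx], model$class_labels) - 1L
  if (anyNA(y)) abort("batch contains labels the classifier does not know")
  y
}

#' Train the scenario classifier
#'
#' Minimizes categorical cross-entropy by minibatch SGD on the training
#' part of the batch, monitoring accuracy on the validation part. The
#' returned weights are those of the best validation epoch; training
#' stops after `patience_epochs` epochs without improvement or at
#' `max_epochs`. The returned model has temperature 1 (uncalibrated);
#' see [calibrate_temperature()].
#'
#' @param network An untrained (or previously trained) `cnn_classifier`.
#' @param batch A [assemble_batch()] result with nonempty train and
#'   validation parts.
#' @param seed Optional integer seed (shuffling and dropout).
#' @param verbose Print per-epoch progress.
#' @return The trained `cnn_classifier`, with `history` (per-epoch
#'   losses/accuracy) and `best_epoch` filled in.
#' @export
train_classifier <- function(network, batch, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(network, "cnn_classifier"),
            inherits(batch, "sim_batch"))
  if (batch$n_loci != network$config$n_loci ||
      batch$n_samples != network$config$n_samples)
    abort("batch image shape does not match the network input shape")
  tr <- batch_images(batch, "train")
  va <- batch_images(batch, "validation")
  if (length(va$idx) == 0)
    abort("validation set is empty but early stopping needs one")
  if (!is.null(seed)) set.seed(seed)
  fit <- cnn_train_cpp(network$params, network$config,
                       tr$images, batch_labels_int(batch, network, tr$idx),
                       va$images, batch_labels_int(batch, network, va$idx),
                       isTRUE(verbose))
  network$params <- fit$params
  network$history <- tibble::as_tibble(fit$history)
  network$best_epoch <- fit$best_epoch
  network$trained <- TRUE
  network$temperature <- 1
  network
}

# images argument -> raw byte matrix (one column per image)
as_image_store <- function(images, config) {
  if (is.raw(images) && is.matrix(images)) return(images)
  if (is.matrix(images)) images <- list(images)
  if (inherits(images, "sim_batch")) return(images$images)
  stopifnot(is.list(images), length(images) > 0)
  out <- matrix(as.raw(0), nrow = config$n_loci * config$n_samples,
                ncol = length(images))
  for (i in seq_along(images)) {
    m <- images[[i]]
    if (nrow(m) != config$n_loci || ncol(m) != config$n_samples)
      abort("image shape does not match the network input shape")
    out[, i] <- encode_raw(m)
  }
  out
}

#' Raw (pre-temperature) logits for a set of images
#'
#' @param model A trained `cnn_classifier`.
#' @param images A `sim_batch`, a list of encoded matrices, or one matrix.
#' @return Numeric matrix, images x classes.
#' @export
classifier_logits <- function(model, images) {
  stopifnot(inherits(model, "cnn_classifier"))
  store <- as_image_store(images, model$config)
  lg <- t(cnn_logits_cpp(model$params, model$config, store))
  colnames(lg) <- model$class_labels
  lg
}

softmax_rows <- function(lg) {
  e <- exp(lg - apply(lg, 1, max))
  e / rowSums(e)
}

#' Calibrate the classifier by temperature scaling
#'
#' Fits a single scalar temperature T > 0 minimizing the negative
#' log-likelihood of `softmax(logits / T)` on held-out labeled images
#' (the batch's validation part by default). Temperature scaling is a
#' monotone transform of the logits, so the predicted class of every
#' input is unchanged; only the confidence is adjusted.
#'
#' @param model A trained `cnn_classifier`.
#' @param batch A labeled `sim_batch`; its validation part is used.
#' @param part Which batch part to calibrate on.
#' @return The model with its `temperature` set.
#' @export
calibrate_temperature <- function(model, batch,
                                  part = c("validation", "train", "all")) {
  stopifnot(inherits(model, "cnn_classifier"), model$trained,
            inherits(batch, "sim_batch"))
  part <- match.arg(part)
  sel <- batch_images(batch, part)
  lg <- classifier_logits(model, sel$images)
  y <- batch_labels_int(batch, model, sel$idx) + 1L
  model$temperature <- fit_temperature(lg, y)
  model
}

#' Fit a softmax temperature to logits and labels
#'
#' One-dimensional minimization of the negative log-likelihood of
#' `softmax(logits / T)` over `T > 0` (searched on the log scale).
#'
#' @param logits Numeric matrix, observations x classes.
#' @param y_index Integer true-class index (1-based) per observation.
#' @return The fitted temperature.
#' @export
fit_temperature <- function(logits, y_index) {
  if (!all(is.finite(logits))) abort("non-finite logits")
  nll <- function(logT) {
    p <- softmax_rows(logits / exp(logT))
    -mean(log(pmax(p[cbind(seq_along(y_index), y_index)], 1e-12)))
  }
  opt <- stats::optimize(nll, c(log(0.01), log(100)), tol = 1e-6)
  exp(opt$minimum)
}

#' Predict scenario probabilities for images
#'
#' Applies the trained network and temperature scaling; probabilities are
#' `softmax(logits / T)`.
#'
#' @param object A trained `cnn_classifier`.
#' @param newdata A `sim_batch`, list of encoded matrices, or one matrix.
#' @param ... Unused.
#' @return A tibble with one row per image: class-probability columns
#'   (named by the class labels) and `pred`, the argmax label.
#' @export
predict.cnn_classifier <- function(object, newdata, ...) {
  lg <- classifier_logits(object, newdata)
  p <- softmax_rows(lg / object$temperature)
  out <- tibble::as_tibble(as.data.frame(p))
  out$pred <- object$class_labels[max.col(p, ties.method = "first")]
  out
}

#' Average a set of per-image predictions
#'
#' Element-wise mean of the class-probability columns, used to pool the
#' predictions of many random subsamples of one empirical matrix into a
#' single summary vector for the ABC step.
#'
#' @param predictions A [predict.cnn_classifier()] tibble.
#' @return Named numeric probability vector (sums to 1).
#' @export
average_prediction <- function(predictions) {
  cols <- setdiff(names(predictions), "pred")
  colMeans(as.matrix(predictions[cols]))
}

#' @export
tidy.cnn_classifier <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  x$history
}

#' @export
glance.cnn_classifier <- function(x, ...) {
  tibble::tibble(
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_accuracy = if (is.null(x$history)) NA_real_
                        else max(x$history$val_accuracy),
    temperature = x$temperature
  )
}

#' Training-history plot
#'
#' @param object A trained `cnn_classifier`.
#' @param ... Unused.
#' @return A ggplot of loss and validation accuracy by epoch.
#' @export
autoplot.cnn_classifier <- function(object, ...) {
  stopifnot(!is.null(object$history))
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
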