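# Compact 8-layer CNN for two-class motor-imagery spectrogram images.

#' Build the classification CNN
#'
#' Architecture: 3 x 3 stride-1 convolution with 8 filters -> (64, 64, 8);
#' 2 x 2 max-pool -> (32, 32, 8); 3 x 3 convolution with 8 filters ->
#' (32, 32, 8); 2 x 2 max-pool -> (16, 16, 8); dense 10; dense 2 with
#' two-way softmax. Dropout sits after each max-pool and the first dense
#' layer. The hidden activation defaults to true ReLU (`max(0, a)`);
#' `activation = "softplus"` (`ln(1 + e^a)`) is selectable.
#'
#' @param filters convolution filter count (default 8).
#' @param dense_units width of the first fully connected layer (default 10).
#' @param activation `"relu"` or `"softplus"`.
#' @param dropout dropout rate (default 0.25).
#' @return an initialized `miaug_net` (He-scaled weights).
#' @export
build_cnn <- function(filters = 8L, dense_units = 10L,
                      activation = c("relu", "softplus"), dropout = 0.25) {
  activation <- match.arg(activation)
  if (filters < 1 || dense_units < 1) stop("filters and dense_units must be >= 1")
  layers <- list(
    layer_conv(filters, stride = 1L, pad = 1L, activation = activation),
    layer_maxpool(2L, dropout = dropout),
    layer_conv(filters, stride = 1L, pad = 1L, activation = activation),
    layer_maxpool(2L, dropout = dropout),
    layer_dense(dense_units, activation = activation, dropout = dropout),
    layer_dense(2L, activation = "softmax"))
  net <- net_init(layers, c(64L, 64L, 3L), init = "he")
  net$role <- "cnn"
  net
}

#' Binary cross-entropy classification loss
#'
#' Mean of `-(y log y~ + (1 - y) log(1 - y~))` over items, where `y~` is
#' the predicted probability of the positive class and `y` the 0/1 truth.
#' Probabilities are clipped at 1e-12 before the logarithm.
#'
#' @param probabilities predicted positive-class probabilities, or a
#'   `2 x n` softmax output matrix (row 2 = positive class).
#' @param truth 0/1 vector (1 = positive class).
#' @return scalar loss.
#' @export
cnn_loss <- function(probabilities, truth) {
  if (is.matrix(probabilities)) probabilities <- probabilities[2, ]
  if (length(probabilities) != length(truth)) stop("length mismatch")
  p <- clip01(probabilities)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' CNN training configuration
#'
#' Stochastic gradient descent with momentum (momentum 0.9 by default;
#' set `momentum = 0` for plain SGD) at learning rate 1e-4.
#'
#' @param learning_rate SGD step size.
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 32).
#' @param momentum SGD momentum term.
#' @param dropout dropout rate.
#' @param filters,dense_units,activation forwarded to [build_cnn()].
#' @param seed integer RNG seed.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(learning_rate = 1e-4, epochs = 50L, batch_size = 32L,
                       momentum = 0.9, dropout = 0.25, filters = 8L,
                       dense_units = 10L, activation = "relu", seed = 1L) {
  if (learning_rate <= 0 || epochs < 1 || batch_size < 1)
    stop("learning rate, epochs, and batch size must be positive")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 dropout = dropout, filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 activation = activation, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Train the classification CNN
#'
#' Minimizes the softmax cross-entropy with momentum SGD on minibatches;
#' inputs are mapped to `[-1, 1]`. Deterministic given the config seed.
#'
#' @param images list of [spectrogram_image()] containing both classes.
#' @param config a [cnn_config()].
#' @return a `cnn_model`: the trained net, per-epoch loss history, class
#'   ordering, and the config.
#' @export
train_cnn <- function(images, config = cnn_config()) {
  labs <- image_labels(images)
  if (length(unique(labs)) < 2)
    stop("training set must contain at least one image per class")
  set.seed(config$seed)
  net <- build_cnn(config$filters, config$dense_units, config$activation,
                   config$dropout)
  opt <- opt_init(net, "sgdm", lr = config$learning_rate,
                  momentum = config$momentum)
  x_all <- image_array(images) * 2 - 1
  onehot <- rbind(as.numeric(labs == CLASS_LEVELS[1]),
                  as.numeric(labs == CLASS_LEVELS[2]))
  n <- length(images)
  bs <- min(config$batch_size, n)
  hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1, n)]
      fw <- net_forward(net, x_all[, , , idx, drop = FALSE], training = TRUE)
      net <- fw$net
      sc <- softmax_ce(fw$out, onehot[, idx, drop = FALSE])
      bk <- net_backward(net, fw$caches, sc$grad, need_dx = FALSE)
      st <- opt_step(opt, net, bk$grads); opt <- st$opt; net <- st$net
      losses <- c(losses, sc$loss)
    }
    hist[ep] <- mean(losses)
  }
  structure(list(net = net, loss_history = hist, classes = CLASS_LEVELS,
                 config = config),
            class = "cnn_model")
}

#' Predict class labels for spectrogram images
#'
#' Runs the CNN in evaluation mode (dropout disabled) and returns argmax
#' labels with the full softmax probability rows.
#'
#' @param model a `cnn_model` from [train_cnn()].
#' @param images list of [spectrogram_image()].
#' @return list with `labels` (character) and `probabilities`
#'   (`n x 2` matrix, columns named by class; rows sum to 1).
#' @export
predict_cnn <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  x <- image_array(images) * 2 - 1
  probs <- t(net_forward(model$net, x, training = FALSE)$out)
  colnames(probs) <- model$classes
  list(labels = model$classes[max.col(probs, ties.method = "first")],
       probabilities = probs)
}

#' @export
predict.cnn_model <- function(object, images, ...) predict_cnn(object, images)

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> filters=%d dense=%d; %d epochs, final loss %.4f\n",
              x$config$filters, x$config$dense_units,
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}
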