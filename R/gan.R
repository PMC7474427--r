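# DCGAN: all-convolutional generator/discriminator pair with batch
# normalization, trained adversarially on spectrogram images.

#' DCGAN training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 2e-4,
#' batch size 128 (clamped to the dataset size when data are scarcer),
#' 20 epochs, batch-norm momentum 0.8, discriminator dropout 0.25. Adam
#' moments use the common GAN convention beta1 = 0.5, beta2 = 0.999.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param beta1,beta2 Adam moment decay rates.
#' @param width channel-width multiplier of both networks; 128 gives the
#'   full 128/256/512/1024 stack, smaller values give proportionally
#'   narrower nets for quick experiments.
#' @param latent_dim latent dimension (100).
#' @param dropout discriminator dropout rate.
#' @param seed integer RNG seed.
#' @return a `gan_config` list.
#' @export
gan_config <- function(learning_rate = 2e-4, batch_size = 128L, epochs = 20L,
                       beta1 = 0.5, beta2 = 0.999, width = 128L,
                       latent_dim = 100L, dropout = 0.25, seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1)
    stop("learning rate, batch size, and epochs must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 width = as.integer(width), latent_dim = as.integer(latent_dim),
                 dropout = dropout, seed = as.integer(seed)),
            class = "gan_config")
}

#' Build the DCGAN generator
#'
#' Six-layer transposed-convolution stack mapping a 100-dimensional latent
#' vector (shaped 100 x 1 x 1) to a 3 x 64 x 64 image: a 4 x 4 projection
#' to (1024, 4, 4), then four stride-2 3 x 3 deconvolutions halving the
#' channel count and doubling the spatial size each step —
#' (512, 8, 8), (256, 16, 16), (128, 32, 32) — and a tanh output layer at
#' (3, 64, 64). Hidden layers use ReLU with batch normalization. The first
#' layer is a 4 x 4 stride-1 projection because no 3 x 3 stride-2
#' deconvolution can map (100, 1, 1) to (1024, 4, 4).
#'
#' @param width channel multiplier (default 128; the hidden stack is
#'   `8w, 4w, 2w, w`).
#' @param latent_dim latent dimension (default 100).
#' @param filters optional explicit hidden channel counts (length 4);
#'   must halve at every step.
#' @return an initialized `miaug_net` (weights N(0, 0.02)).
#' @export
build_generator <- function(width = 128L, latent_dim = 100L, filters = NULL) {
  if (is.null(filters)) filters <- width * c(8L, 4L, 2L, 1L)
  if (length(filters) != 4 || any(filters[-1] * 2L != filters[-4]))
    stop("generator channel counts must halve at every deconvolution")
  layers <- list(
    layer_convt(filters[1], kernel = 4L, stride = 1L, pad = 0L, outpad = 0L,
                activation = "relu", batchnorm = TRUE),
    layer_convt(filters[2], activation = "relu", batchnorm = TRUE),
    layer_convt(filters[3], activation = "relu", batchnorm = TRUE),
    layer_convt(filters[4], activation = "relu", batchnorm = TRUE),
    layer_convt(3L, activation = "tanh", batchnorm = FALSE))
  net <- net_init(layers, c(1L, 1L, latent_dim), init = "dcgan")
  net$role <- "generator"
  net
}

#' Build the DCGAN discriminator
#'
#' Four stride-2 3 x 3 convolutions with leaky-ReLU activations and
#' dropout — (128, 32, 32), (256, 16, 16), (512, 8, 8), (1024, 4, 4),
#' batch-normalized from the second layer on — flattened to 16384 features
#' and mapped to a single sigmoid real-vs-generated score.
#'
#' @param width channel multiplier (default 128; the stack is
#'   `w, 2w, 4w, 8w`).
#' @param dropout dropout rate after each convolution (default 0.25).
#' @param filters optional explicit channel counts (length 4); must double
#'   at every step.
#' @return an initialized `miaug_net`.
#' @export
build_discriminator <- function(width = 128L, dropout = 0.25, filters = NULL) {
  if (is.null(filters)) filters <- width * c(1L, 2L, 4L, 8L)
  if (length(filters) != 4 || any(filters[-4] * 2L != filters[-1]))
    stop("discriminator channel counts must double at every convolution")
  layers <- list(
    layer_conv(filters[1], stride = 2L, activation = "lrelu",
               batchnorm = FALSE, dropout = dropout),
    layer_conv(filters[2], stride = 2L, activation = "lrelu",
               batchnorm = TRUE, dropout = dropout),
    layer_conv(filters[3], stride = 2L, activation = "lrelu",
               batchnorm = TRUE, dropout = dropout),
    layer_conv(filters[4], stride = 2L, activation = "lrelu",
               batchnorm = TRUE, dropout = dropout),
    layer_dense(1L, activation = "sigmoid"))
  net <- net_init(layers, c(64L, 64L, 3L), init = "dcgan")
  net$role <- "discriminator"
  net
}

#' Adversarial losses from discriminator scores
#'
#' `loss_d` is the binary cross-entropy of the discriminator with real
#' labels 1 and fake labels 0, averaged over all scored items. `loss_g`
#' is the non-saturating generator loss `-mean(log D(G(z)))`; `minimax`
#' reports the original value function
#' `mean(log D(x)) + mean(log(1 - D(G(z))))`.
#'
#' @param d_real,d_fake discriminator scores in `(0, 1)`.
#' @return list with `loss_d`, `loss_g`, `minimax`.
#' @export
gan_losses <- function(d_real, d_fake) {
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1))
    stop("scores must lie strictly inside (0, 1)")
  loss_d <- -(sum(log(d_real)) + sum(log(1 - d_fake))) /
    (length(d_real) + length(d_fake))
  loss_g <- -mean(log(d_fake))
  minimax <- mean(log(d_real)) + mean(log(1 - d_fake))
  list(loss_d = loss_d, loss_g = loss_g, minimax = minimax)
}

sample_latent <- function(n, latent_dim = 100L) {
  array(stats::rnorm(n * latent_dim), dim = c(1L, 1L, latent_dim, n))
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) { a[[i]] <- b[[i]]; next }
    for (p in names(b[[i]])) {
      a[[i]][[p]] <- if (is.null(a[[i]][[p]])) b[[i]][[p]]
                     else a[[i]][[p]] + b[[i]][[p]]
    }
  }
  a
}

#' Train a DCGAN on spectrogram images
#'
#' Alternating minibatch training: the discriminator takes an Adam step on
#' a real batch (label 1) plus a generated batch (label 0); the generator
#' then takes an Adam step on the non-saturating loss through a fresh
#' latent batch. Images are mapped to `[-1, 1]` to match the tanh output.
#' One model is trained per class so samples inherit an unambiguous label.
#' The run is deterministic given the config seed.
#'
#' @param images list of [spectrogram_image()] (a single class).
#' @param config a [gan_config()].
#' @return a `gan_state`: generator and discriminator nets, per-epoch loss
#'   history (`epoch`, `loss_d`, `loss_g`), epoch counter, and config.
#' @export
train_dcgan <- function(images, config = gan_config()) {
  if (length(images) == 0) stop("image set must be non-empty")
  set.seed(config$seed)
  n <- length(images)
  bs <- min(config$batch_size, n)
  x_all <- image_array(images) * 2 - 1
  G <- build_generator(config$width, config$latent_dim)
  D <- build_discriminator(config$width, config$dropout)
  optG <- opt_init(G, "adam", lr = config$learning_rate,
                   beta1 = config$beta1, beta2 = config$beta2)
  optD <- opt_init(D, "adam", lr = config$learning_rate,
                   beta1 = config$beta1, beta2 = config$beta2)
  hist <- data.frame(epoch = integer(), loss_d = numeric(), loss_g = numeric())
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ld <- lg <- c()
    for (start in seq(1, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1, n)]
      m <- length(idx)
      if (m < 2) next  # batch statistics undefined for a single item
      xb <- x_all[, , , idx, drop = FALSE]
      # --- discriminator step
      z <- sample_latent(m, config$latent_dim)
      fg <- net_forward(G, z, training = TRUE)
      G <- fg$net
      fake <- fg$out
      fr <- net_forward(D, xb, training = TRUE); D <- fr$net
      ff <- net_forward(D, fake, training = TRUE); D <- ff$net
      s_real <- clip01(fr$out); s_fake <- clip01(ff$out)
      losses <- gan_losses(s_real, s_fake)
      ntot <- 2 * m
      g_real <- -(1 / s_real) / ntot; dim(g_real) <- dim(fr$out)
      g_fake <- (1 / (1 - s_fake)) / ntot; dim(g_fake) <- dim(ff$out)
      gr <- net_backward(D, fr$caches, g_real, need_dx = FALSE)$grads
      gf <- net_backward(D, ff$caches, g_fake, need_dx = FALSE)$grads
      st <- opt_step(optD, D, grads_add(gr, gf)); optD <- st$opt; D <- st$net
      # --- generator step (non-saturating loss, fresh latents)
      z2 <- sample_latent(m, config$latent_dim)
      fg2 <- net_forward(G, z2, training = TRUE)
      G <- fg2$net
      fd <- net_forward(D, fg2$out, training = TRUE)
      s2 <- clip01(fd$out)
      g_s <- -(1 / s2) / m; dim(g_s) <- dim(fd$out)
      bd <- net_backward(D, fd$caches, g_s)
      gg <- net_backward(G, fg2$caches, bd$dx)$grads
      st <- opt_step(optG, G, gg); optG <- st$opt; G <- st$net
      ld <- c(ld, losses$loss_d)
      lg <- c(lg, -mean(log(s2)))
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss_d = mean(ld),
                                   loss_g = mean(lg)))
  }
  structure(list(generator = G, discriminator = D, loss_history = hist,
                 epochs_done = config$epochs, config = config),
            class = "gan_state")
}

#' @export
print.gan_state <- function(x, ...) {
  cat(sprintf("<gan_state> width=%d, %d epochs; final loss_d=%.3f loss_g=%.3f\n",
              x$config$width, x$epochs_done,
              utils::tail(x$loss_history$loss_d, 1),
              utils::tail(x$loss_history$loss_g, 1)))
  invisible(x)
}

#' Sample images from a trained DCGAN generator
#'
#' Draws latent vectors from the standard normal prior, runs the generator
#' in evaluation mode (batch norm uses running statistics), and rescales
#' the tanh output linearly from `[-1, 1]` to `[0, 1]`.
#'
#' @param state a `gan_state` from [train_dcgan()].
#' @param n number of images (> 0).
#' @param label class label attached to every sample.
#' @param seed integer RNG seed.
#' @param subject_id subject identifier.
#' @return list of [spectrogram_image()] with provenance `"dcgan"`.
#' @export
sample_generated <- function(state, n, label, seed = 1L,
                             subject_id = NA_character_) {
  stopifnot(inherits(state, "gan_state"))
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  z <- sample_latent(n, state$config$latent_dim)
  out <- net_forward(state$generator, z, training = FALSE)$out
  px <- pmin(pmax((out + 1) / 2, 0), 1)
  array_to_images(px, label, "dcgan", subject_id)
}
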