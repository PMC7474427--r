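# Autoencoder and variational autoencoder augmenters. Both share the
# DCGAN convolutional stacks: the encoder mirrors the discriminator, the
# decoder mirrors the generator, with a 100-dimensional bottleneck.

#' Autoencoder / VAE training configuration
#'
#' Adam with the same defaults as the adversarial models (learning rate
#' 2e-4, batch size 128 clamped to the data, 20 epochs).
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param width channel multiplier of the conv stacks (default 16).
#' @param latent_dim bottleneck dimension (100).
#' @param seed integer RNG seed.
#' @return an `ae_config` list.
#' @export
ae_config <- function(learning_rate = 2e-4, batch_size = 128L, epochs = 20L,
                      width = 16L, latent_dim = 100L, seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1)
    stop("learning rate, batch size, and epochs must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), width = as.integer(width),
                 latent_dim = as.integer(latent_dim), seed = as.integer(seed)),
            class = "ae_config")
}

ae_encoder_layers <- function(width, out_units) {
  list(
    layer_conv(width, stride = 2L, activation = "lrelu"),
    layer_conv(2L * width, stride = 2L, activation = "lrelu"),
    layer_conv(4L * width, stride = 2L, activation = "lrelu"),
    layer_conv(8L * width, stride = 2L, activation = "lrelu"),
    layer_dense(out_units, activation = "linear"))
}

ae_decoder_layers <- function(width) {
  list(
    layer_convt(8L * width, kernel = 4L, stride = 1L, pad = 0L, outpad = 0L,
                activation = "relu", batchnorm = TRUE),
    layer_convt(4L * width, activation = "relu", batchnorm = TRUE),
    layer_convt(2L * width, activation = "relu", batchnorm = TRUE),
    layer_convt(width, activation = "relu", batchnorm = TRUE),
    layer_convt(3L, activation = "tanh"))
}

#' Build an autoencoder
#'
#' Deterministic 100-dimensional bottleneck: a strided conv encoder
#' mirroring the discriminator stack and a deconv decoder mirroring the
#' generator stack (tanh output).
#'
#' @param width channel multiplier.
#' @param latent_dim bottleneck dimension.
#' @return an `ae_model` with untrained `encoder` and `decoder` nets.
#' @export
build_autoencoder <- function(width = 16L, latent_dim = 100L) {
  structure(list(
    kind = "ae",
    encoder = net_init(ae_encoder_layers(width, latent_dim), c(64L, 64L, 3L),
                       init = "he"),
    decoder = net_init(ae_decoder_layers(width), c(1L, 1L, latent_dim),
                       init = "dcgan"),
    latent_dim = as.integer(latent_dim)),
    class = "ae_model")
}

#' Build a variational autoencoder
#'
#' Same stacks as [build_autoencoder()], but the encoder emits a mean and
#' a log-variance for each latent coordinate; training adds the
#' Kullback-Leibler term to a standard normal prior and samples latents by
#' reparameterization.
#'
#' @param width channel multiplier.
#' @param latent_dim latent dimension.
#' @return an `ae_model` with `kind = "vae"`.
#' @export
build_vae <- function(width = 16L, latent_dim = 100L) {
  m <- build_autoencoder(width, latent_dim)
  m$kind <- "vae"
  m$encoder <- net_init(ae_encoder_layers(width, 2L * latent_dim),
                        c(64L, 64L, 3L), init = "he")
  m
}

#' Kullback-Leibler divergence of a diagonal Gaussian from N(0, I)
#'
#' `-0.5 * sum(1 + logvar - mu^2 - exp(logvar))`, averaged over the batch;
#' always >= 0 and exactly 0 at `mu = 0`, `logvar = 0`.
#'
#' @param mu,logvar `d x n` matrices of per-item Gaussian parameters.
#' @return scalar divergence.
#' @export
vae_kl <- function(mu, logvar) {
  -0.5 * sum(1 + logvar - mu^2 - exp(logvar)) / ncol(as.matrix(mu))
}

ae_reconstruct <- function(model, x, training = FALSE) {
  fe <- net_forward(model$encoder, x, training)
  code <- fe$out
  mu <- logvar <- eps <- NULL
  if (model$kind == "vae") {
    d <- model$latent_dim
    mu <- code[seq_len(d), , drop = FALSE]
    logvar <- pmin(code[d + seq_len(d), , drop = FALSE], 10)
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    z <- mu + exp(0.5 * logvar) * eps
  } else {
    z <- code
  }
  zin <- array(z, dim = c(1L, 1L, nrow(z), ncol(z)))
  fd <- net_forward(model$decoder, zin, training)
  list(fe = fe, fd = fd, recon = fd$out, z = z, mu = mu, logvar = logvar,
       eps = eps)
}

#' Train an autoencoder or variational autoencoder
#'
#' Minimizes the mean-squared reconstruction error in tanh space
#' (plus the KL term for the VAE) with Adam. For the plain autoencoder the
#' latent codes of the training images are stored so that sampling can
#' perturb real encodings. Deterministic given the config seed.
#'
#' @param kind `"ae"` or `"vae"`.
#' @param images list of [spectrogram_image()].
#' @param config an [ae_config()].
#' @return a trained `ae_model` with `loss_history` (per-epoch total loss)
#'   and, for `"ae"`, the training `codes`.
#' @export
train_autoencoder <- function(kind = c("ae", "vae"), images,
                              config = ae_config()) {
  kind <- match.arg(kind)
  if (length(images) == 0) stop("image set must be non-empty")
  set.seed(config$seed)
  model <- if (kind == "ae") build_autoencoder(config$width, config$latent_dim)
           else build_vae(config$width, config$latent_dim)
  optE <- opt_init(model$encoder, "adam", lr = config$learning_rate)
  optD <- opt_init(model$decoder, "adam", lr = config$learning_rate)
  x_all <- image_array(images) * 2 - 1
  n <- length(images)
  bs <- min(config$batch_size, n)
  hist <- numeric(config$epochs)
  d <- model$latent_dim
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1, n)]
      if (length(idx) < 2) next
      xb <- x_all[, , , idx, drop = FALSE]
      rc <- ae_reconstruct(model, xb, training = TRUE)
      model$encoder <- rc$fe$net
      model$decoder <- rc$fd$net
      m <- length(idx)
      resid <- rc$recon - xb
      loss <- mean(resid^2)
      drecon <- 2 * resid / length(resid)
      bd <- net_backward(model$decoder, rc$fd$caches, drecon)
      dz <- matrix(bd$dx, nrow = d)
      if (kind == "vae") {
        kl <- vae_kl(rc$mu, rc$logvar)
        loss <- loss + kl
        dmu <- dz + rc$mu / m
        dlv <- dz * rc$eps * 0.5 * exp(0.5 * rc$logvar) -
          0.5 * (1 - exp(rc$logvar)) / m
        denc <- rbind(dmu, dlv)
      } else {
        denc <- dz
      }
      be <- net_backward(model$encoder, rc$fe$caches, denc, need_dx = FALSE)
      st <- opt_step(optD, model$decoder, bd$grads)
      optD <- st$opt; model$decoder <- st$net
      st <- opt_step(optE, model$encoder, be$grads)
      optE <- st$opt; model$encoder <- st$net
      losses <- c(losses, loss)
    }
    hist[ep] <- mean(losses)
  }
  model$loss_history <- hist
  model$config <- config
  if (kind == "ae") {
    fe <- net_forward(model$encoder, x_all, training = FALSE)
    model$codes <- fe$out
  }
  model
}

#' Sample images from a trained autoencoder or VAE
#'
#' VAE: latents are drawn from the standard normal prior and decoded.
#' Plain autoencoder: a plain AE has no sampling prior, so stored training
#' encodings are perturbed with spherical Gaussian noise (scaled to half
#' the average per-coordinate spread of the codes) and decoded.
#'
#' @param model a trained `ae_model`.
#' @param n number of images (> 0).
#' @param label class label attached to every sample.
#' @param seed integer RNG seed.
#' @param subject_id subject identifier.
#' @return list of [spectrogram_image()] with provenance `"ae"` or `"vae"`.
#' @export
sample_autoencoder <- function(model, n, label, seed = 1L,
                               subject_id = NA_character_) {
  stopifnot(inherits(model, "ae_model"))
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  d <- model$latent_dim
  if (model$kind == "vae") {
    z <- matrix(stats::rnorm(d * n), d, n)
  } else {
    if (is.null(model$codes)) stop("model has no stored codes; train it first")
    pick <- sample.int(ncol(model$codes), n, replace = TRUE)
    base <- model$codes[, pick, drop = FALSE]
    sigma <- 0.5 * mean(apply(model$codes, 1, stats::sd))
    z <- base + matrix(stats::rnorm(d * n, 0, sigma), d, n)
  }
  zin <- array(z, dim = c(1L, 1L, d, n))
  out <- net_forward(model$decoder, zin, training = FALSE)$out
  px <- pmin(pmax((out + 1) / 2, 0), 1)
  array_to_images(px, label, model$kind, subject_id)
}
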