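#' @useDynLib miaug, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal sequential network engine used by the generative models and the
# classifier. Activations are (H, W, C, N) arrays (or D x N matrices after
# flattening); weights are (k, k, C_in, C_out) arrays. Convolution and
# pooling kernels live in src/conv.cpp; everything else is vectorized R.
# ---------------------------------------------------------------------------

layer_conv <- function(filters, kernel = 3L, stride = 1L, pad = 1L,
                       activation = "relu", batchnorm = FALSE, dropout = 0) {
  list(type = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad),
       activation = activation, batchnorm = batchnorm, dropout = dropout)
}

layer_convt <- function(filters, kernel = 3L, stride = 2L, pad = 1L,
                        outpad = 1L, activation = "relu", batchnorm = FALSE,
                        dropout = 0) {
  list(type = "convt", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad),
       outpad = as.integer(outpad), activation = activation,
       batchnorm = batchnorm, dropout = dropout)
}

layer_maxpool <- function(size = 2L, dropout = 0) {
  list(type = "maxpool", size = as.integer(size), dropout = dropout)
}

layer_dense <- function(units, activation = "linear", dropout = 0) {
  list(type = "dense", units = as.integer(units), activation = activation,
       dropout = dropout)
}

#' Initialize a sequential network
#'
#' Allocates parameters for a list of layer descriptors given the input
#' shape. `init = "dcgan"` draws weights from N(0, 0.02) (the usual GAN
#' convention); `init = "he"` scales by fan-in for rectifier nets.
#'
#' @param layers list of layer descriptors (`layer_conv()`, `layer_convt()`,
#'   `layer_maxpool()`, `layer_dense()`).
#' @param input_shape integer vector `c(H, W, C)`.
#' @param init weight initialization scheme, `"dcgan"` or `"he"`.
#' @return a `miaug_net` object holding layers with parameters and shapes.
#' @keywords internal
net_init <- function(layers, input_shape, init = c("dcgan", "he")) {
  init <- match.arg(init)
  shape <- as.integer(input_shape)  # c(H, W, C) or scalar D
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      cin <- shape[3]
      sd <- if (init == "dcgan") 0.02 else sqrt(2 / (l$kernel^2 * cin))
      l$W <- array(stats::rnorm(l$kernel^2 * cin * l$filters, 0, sd),
                   dim = c(l$kernel, l$kernel, cin, l$filters))
      l$b <- numeric(l$filters)
      ho <- (shape[1] + 2L * l$pad - l$kernel) %/% l$stride + 1L
      wo <- (shape[2] + 2L * l$pad - l$kernel) %/% l$stride + 1L
      shape <- c(ho, wo, l$filters)
    } else if (l$type == "convt") {
      cin <- shape[3]  # input channels = 4th dim of weight array
      sd <- if (init == "dcgan") 0.02 else sqrt(2 / (l$kernel^2 * cin))
      l$W <- array(stats::rnorm(l$kernel^2 * l$filters * cin, 0, sd),
                   dim = c(l$kernel, l$kernel, l$filters, cin))
      l$b <- numeric(l$filters)
      l$in_shape <- shape
      ho <- (shape[1] - 1L) * l$stride - 2L * l$pad + l$kernel + l$outpad
      wo <- (shape[2] - 1L) * l$stride - 2L * l$pad + l$kernel + l$outpad
      l$out_hw <- c(ho, wo)
      shape <- c(ho, wo, l$filters)
    } else if (l$type == "maxpool") {
      shape <- c(shape[1] %/% l$size, shape[2] %/% l$size, shape[3])
    } else if (l$type == "dense") {
      d <- prod(shape)
      sd <- if (init == "dcgan") 0.02 else sqrt(2 / d)
      l$W <- matrix(stats::rnorm(l$units * d, 0, sd), l$units, d)
      l$b <- numeric(l$units)
      shape <- l$units
    }
    if (isTRUE(l$batchnorm)) {
      nc <- if (l$type == "dense") l$units else l$filters
      l$gamma <- rep(1, nc); l$beta <- rep(0, nc)
      l$run_mean <- rep(0, nc); l$run_var <- rep(1, nc)
    }
    l$out_shape <- shape
    layers[[i]] <- l
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape)),
            class = "miaug_net")
}

net_out_shapes <- function(net) lapply(net$layers, `[[`, "out_shape")

# -- activations ------------------------------------------------------------

act_fwd <- function(z, kind) {
  switch(kind,
    linear   = z,
    relu     = pmax(z, 0),
    lrelu    = z * (0.2 + 0.8 * (z > 0)),
    tanh     = tanh(z),
    sigmoid  = 1 / (1 + exp(-z)),
    softplus = log1p(exp(pmin(z, 30))) + pmax(z - 30, 0),
    softmax  = {
      zm <- sweep(z, 2, apply(z, 2, max), "-")
      e <- exp(zm); sweep(e, 2, colSums(e), "/")
    },
    stop("unknown activation: ", kind))
}

# da/dz given pre-activation z and output a; softmax is handled jointly with
# cross-entropy (callers pass dL/dz directly), so its derivative is identity.
act_bwd <- function(dout, z, a, kind) {
  switch(kind,
    linear   = dout,
    relu     = dout * (z > 0),
    lrelu    = dout * (0.2 + 0.8 * (z > 0)),
    tanh     = dout * (1 - a * a),
    sigmoid  = dout * a * (1 - a),
    softplus = dout / (1 + exp(-z)),
    softmax  = dout,
    stop("unknown activation: ", kind))
}

# -- batch norm (per channel over batch and spatial dims) -------------------

bn_channels <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) list(hw = 1L, C = nrow(x), N = ncol(x))
  else list(hw = d[1] * d[2], C = d[3], N = d[4])
}

bn_fwd <- function(x, l, training, eps = 1e-5, momentum = 0.8) {
  g <- bn_channels(x)
  M <- matrix(x, nrow = g$hw)
  if (training) {
    cm <- colMeans(M); cm2 <- colMeans(M * M)
    mu <- rowMeans(matrix(cm, nrow = g$C))
    ex2 <- rowMeans(matrix(cm2, nrow = g$C))
    v <- pmax(ex2 - mu^2, 0)
  } else {
    mu <- l$run_mean; v <- l$run_var
  }
  sd_ <- sqrt(v + eps)
  # per-channel values expanded over the spatial dim recycle over the batch
  xhat <- (M - rep(mu, each = g$hw)) * rep(1 / sd_, each = g$hw)
  y <- xhat * rep(l$gamma, each = g$hw) + rep(l$beta, each = g$hw)
  dim(y) <- dim(x)
  st <- NULL
  if (training) st <- list(mean = momentum * l$run_mean + (1 - momentum) * mu,
                           var  = momentum * l$run_var + (1 - momentum) * v)
  list(y = y, cache = list(xhat = xhat, sd = sd_, g = g), new_stats = st)
}

bn_bwd <- function(dout, l, cache) {
  g <- cache$g
  dY <- matrix(dout, nrow = g$hw)
  xhat <- cache$xhat
  m <- g$hw * g$N
  per_c <- function(M) rowSums(matrix(colSums(M), nrow = g$C))
  dgamma <- per_c(dY * xhat)
  dbeta <- per_c(dY)
  dxhat <- dY * rep(l$gamma, each = g$hw)
  s1 <- per_c(dxhat); s2 <- per_c(dxhat * xhat)
  dx <- (m * dxhat - rep(s1, each = g$hw) - xhat * rep(s2, each = g$hw)) *
    rep(1 / (m * cache$sd), each = g$hw)
  dim(dx) <- dim(dout)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# -- forward / backward -----------------------------------------------------

#' Run a forward pass
#' @param net a `miaug_net`.
#' @param x input batch, `(H, W, C, N)` array.
#' @param training logical; enables batch statistics and dropout.
#' @return list with `out` and per-layer `caches` (for `net_backward`).
#' @keywords internal
net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    cache <- list(x = x)
    if (l$type == "conv") {
      z <- .conv_fwd(x, l$W, l$b, l$stride, l$pad)
    } else if (l$type == "convt") {
      z <- .conv_bwd_input(x, l$W, l$stride, l$pad, l$out_hw[1], l$out_hw[2])
      hw <- l$out_hw[1] * l$out_hw[2]
      z <- z + rep(l$b, each = hw)  # recycles over the batch dimension
    } else if (l$type == "maxpool") {
      mp <- .maxpool_fwd(x, l$size)
      cache$idx <- mp$idx
      cache$in_hw <- dim(x)[1:2]
      x <- mp$y
      if (training && l$dropout > 0) {
        mask <- (stats::runif(length(x)) >= l$dropout) / (1 - l$dropout)
        dim(mask) <- dim(x)
        cache$mask <- mask
        x <- x * mask
      }
      caches[[i]] <- cache
      next
    } else if (l$type == "dense") {
      xf <- if (is.matrix(x)) x else matrix(x, ncol = dim(x)[4])
      cache$xf <- xf
      z <- l$W %*% xf + l$b
    }
    if (isTRUE(l$batchnorm)) {
      bn <- bn_fwd(z, l, training)
      cache$z_prebn <- z
      cache$bn <- bn$cache
      z <- bn$y
      if (training && !is.null(bn$new_stats)) {
        net$layers[[i]]$run_mean <- bn$new_stats$mean
        net$layers[[i]]$run_var <- bn$new_stats$var
      }
    }
    a <- act_fwd(z, l$activation)
    if (training && l$dropout > 0) {
      mask <- (stats::runif(length(a)) >= l$dropout) / (1 - l$dropout)
      dim(mask) <- dim(a)
      cache$mask <- mask
      a <- a * mask
    }
    cache$z <- z; cache$a <- a
    caches[[i]] <- cache
    x <- a
  }
  list(out = x, caches = caches, net = net)
}

#' Backpropagate through a network
#'
#' `dout` is the gradient of the loss w.r.t. the network output
#' (post-activation), except for a final softmax layer where by convention
#' the caller supplies the gradient w.r.t. the pre-softmax logits.
#' @return list with per-layer gradient lists and `dx` (gradient at input).
#' @keywords internal
net_backward <- function(net, caches, dout, need_dx = TRUE) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- caches[[i]]
    if (l$type == "maxpool") {
      if (!is.null(cache$mask)) dout <- dout * cache$mask
      dout <- .maxpool_bwd(dout, cache$idx, cache$in_hw[1], cache$in_hw[2])
      next
    }
    if (!is.null(cache$mask)) dout <- dout * cache$mask
    dz <- act_bwd(dout, cache$z, cache$a, l$activation)
    gl <- list()
    if (isTRUE(l$batchnorm)) {
      bb <- bn_bwd(dz, l, cache$bn)
      gl$gamma <- bb$dgamma; gl$beta <- bb$dbeta
      dz <- bb$dx
    }
    if (l$type == "conv") {
      gl$W <- .conv_bwd_weights(cache$x, dz, l$kernel, l$stride, l$pad)
      hw <- dim(dz)[1] * dim(dz)[2]
      gl$b <- rowSums(matrix(colSums(matrix(dz, nrow = hw)), nrow = l$filters))
      if (i > 1 || need_dx)
        dout <- .conv_bwd_input(dz, l$W, l$stride, l$pad,
                                dim(cache$x)[1], dim(cache$x)[2])
    } else if (l$type == "convt") {
      gl$W <- .conv_bwd_weights(dz, cache$x, l$kernel, l$stride, l$pad)
      hw <- dim(dz)[1] * dim(dz)[2]
      gl$b <- rowSums(matrix(colSums(matrix(dz, nrow = hw)), nrow = l$filters))
      if (i > 1 || need_dx)
        dout <- .conv_fwd(dz, l$W, numeric(dim(l$W)[4]), l$stride, l$pad)
    } else if (l$type == "dense") {
      gl$W <- dz %*% t(cache$xf)
      gl$b <- rowSums(dz)
      dout <- t(l$W) %*% dz
      if (!is.matrix(cache$x)) dim(dout) <- dim(cache$x)
    }
    grads[[i]] <- gl
  }
  list(grads = grads, dx = dout)
}

# -- optimizers -------------------------------------------------------------

PARAM_NAMES <- c("W", "b", "gamma", "beta")

#' @keywords internal
opt_init <- function(net, method = c("adam", "sgdm"), lr = 2e-4,
                     beta1 = 0.5, beta2 = 0.999, momentum = 0.9,
                     eps = 1e-8) {
  method <- match.arg(method)
  state <- lapply(net$layers, function(l) {
    s <- list()
    for (p in PARAM_NAMES) if (!is.null(l[[p]])) {
      s[[p]] <- list(m = l[[p]] * 0, v = l[[p]] * 0)
    }
    s
  })
  list(method = method, lr = lr, beta1 = beta1, beta2 = beta2,
       momentum = momentum, eps = eps, t = 0L, state = state)
}

#' @keywords internal
opt_step <- function(opt, net, grads) {
  opt$t <- opt$t + 1L
  for (i in seq_along(net$layers)) {
    gl <- grads[[i]]
    if (is.null(gl)) next
    for (p in names(gl)) {
      g <- gl[[p]]
      st <- opt$state[[i]][[p]]
      if (opt$method == "adam") {
        st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
        st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
        mhat <- st$m / (1 - opt$beta1^opt$t)
        vhat <- st$v / (1 - opt$beta2^opt$t)
        net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
          opt$lr * mhat / (sqrt(vhat) + opt$eps)
      } else {
        st$m <- opt$momentum * st$m + g
        net$layers[[i]][[p]] <- net$layers[[i]][[p]] - opt$lr * st$m
      }
      opt$state[[i]][[p]] <- st
    }
  }
  list(opt = opt, net = net)
}

# -- losses -----------------------------------------------------------------

clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# mean binary cross-entropy and its gradient w.r.t. the scores
bce_loss <- function(scores, labels) {
  s <- clip01(scores)
  n <- length(s)
  loss <- -mean(labels * log(s) + (1 - labels) * log(1 - s))
  grad <- (-(labels / s) + (1 - labels) / (1 - s)) / n
  dim(grad) <- dim(scores)
  list(loss = loss, grad = grad)
}

# softmax cross-entropy: probs (K x N), onehot (K x N); grad is w.r.t. logits
softmax_ce <- function(probs, onehot) {
  p <- clip01(probs)
  n <- ncol(p)
  loss <- -sum(onehot * log(p)) / n
  grad <- (probs - onehot) / n
  list(loss = loss, grad = grad)
}
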