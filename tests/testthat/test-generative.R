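# DCGAN, autoencoder, and VAE: architecture, losses, training contracts.
# Full-width (128) layer-by-layer conformance is exercised in
# test-acceptance.R; routine tests use narrow nets for speed.

test_that("generator layer dimensions scale by halving/doubling", {
  g <- build_generator(width = 8)
  shp <- miaug:::net_out_shapes(g)
  expect_identical(shp[[1]], c(4L, 4L, 64L))
  expect_identical(shp[[2]], c(8L, 8L, 32L))
  expect_identical(shp[[3]], c(16L, 16L, 16L))
  expect_identical(shp[[4]], c(32L, 32L, 8L))
  expect_identical(shp[[5]], c(64L, 64L, 3L))
  expect_error(build_generator(filters = c(64, 32, 20, 8)), "halve")
})

test_that("discriminator flattens to a single sigmoid score", {
  d <- build_discriminator(width = 8)
  shp <- miaug:::net_out_shapes(d)
  expect_identical(shp[[1]], c(32L, 32L, 8L))
  expect_identical(shp[[4]], c(4L, 4L, 64L))
  expect_identical(shp[[5]], 1L)
  expect_identical(dim(d$layers[[5]]$W), c(1L, 1024L))
  expect_error(build_discriminator(filters = c(8, 16, 30, 64)), "double")
})

test_that("zero-parameter networks give the fixed-point outputs", {
  g <- build_generator(width = 4)
  for (i in seq_along(g$layers)) {
    g$layers[[i]]$W[] <- 0; g$layers[[i]]$b[] <- 0
    if (!is.null(g$layers[[i]]$beta)) g$layers[[i]]$beta[] <- 0
  }
  out <- miaug:::net_forward(g, miaug:::sample_latent(2), training = FALSE)$out
  expect_true(all(out == 0))  # tanh(0) = 0
  d <- build_discriminator(width = 4)
  for (i in seq_along(d$layers)) { d$layers[[i]]$W[] <- 0; d$layers[[i]]$b[] <- 0 }
  x <- array(stats::runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  expect_equal(as.numeric(miaug:::net_forward(d, x)$out), c(0.5, 0.5))
})

test_that("adversarial losses match hand and brute-force evaluation", {
  l <- gan_losses(rep(0.5, 4), rep(0.5, 4))
  expect_equal(l$loss_d, log(2), tolerance = 1e-12)
  # perfect discrimination drives the loss to zero
  eps <- 1e-8
  expect_lt(gan_losses(rep(1 - eps, 3), rep(eps, 3))$loss_d, 1e-6)
  set.seed(12)
  dr <- stats::runif(20, 0.05, 0.95)
  df <- stats::runif(30, 0.05, 0.95)
  # brute force: per-element binary cross-entropy with labels 1 and 0
  y <- c(rep(1, 20), rep(0, 30)); s <- c(dr, df)
  bf <- -sum(y * log(s) + (1 - y) * log(1 - s)) / length(s)
  expect_equal(gan_losses(dr, df)$loss_d, bf, tolerance = 1e-10)
  expect_error(gan_losses(c(0.5, 1), c(0.2)), "inside")
})

test_that("dcgan training is reproducible and records per-epoch losses", {
  imgs <- fixture_images(6, seed = 77)[1:8]
  cfg <- gan_config(width = 4, epochs = 2, batch_size = 8, seed = 3)
  s1 <- train_dcgan(imgs, cfg)
  s2 <- train_dcgan(imgs, cfg)
  expect_identical(s1$generator$layers, s2$generator$layers)
  expect_identical(s1$loss_history, s2$loss_history)
  expect_identical(nrow(s1$loss_history), 2L)
  expect_error(train_dcgan(list(), cfg), "non-empty")
})

test_that("generated samples are valid images with dcgan provenance", {
  imgs <- fixture_images(6, seed = 77)[1:8]
  st <- train_dcgan(imgs, gan_config(width = 4, epochs = 1, batch_size = 8,
                                     seed = 3))
  g1 <- sample_generated(st, 5, "right", seed = 4)
  g2 <- sample_generated(st, 5, "right", seed = 4)
  expect_length(g1, 5)
  expect_identical(g1, g2)
  for (im in g1) {
    expect_identical(dim(im$pixels), c(64L, 64L, 3L))
    expect_true(all(im$pixels >= 0 & im$pixels <= 1))
    expect_identical(im$provenance, "dcgan")
    expect_identical(im$label, "right")
  }
  expect_error(sample_generated(st, 0, "right"), "positive")
})

test_that("a zero-parameter generator samples mid-range gray", {
  st <- train_dcgan(fixture_images(6, seed = 77)[1:8],
                    gan_config(width = 4, epochs = 1, batch_size = 8, seed = 3))
  for (i in seq_along(st$generator$layers)) {
    st$generator$layers[[i]]$W[] <- 0
    st$generator$layers[[i]]$b[] <- 0
    if (!is.null(st$generator$layers[[i]]$beta))
      st$generator$layers[[i]]$beta[] <- 0
  }
  out <- sample_generated(st, 2, "left", seed = 1)
  expect_true(all(vapply(out, function(im) all(im$pixels == 0.5), TRUE)))
})

test_that("autoencoder reconstructs the right shape and VAE KL is sane", {
  ae <- build_autoencoder(width = 4)
  x <- array(stats::runif(64 * 64 * 3 * 2) * 2 - 1, c(64, 64, 3, 2))
  rc <- miaug:::ae_reconstruct(ae, x)
  expect_identical(dim(rc$recon), c(64L, 64L, 3L, 2L))
  mu <- matrix(rnorm(20), 10, 2); lv <- matrix(rnorm(20, 0, 0.3), 10, 2)
  expect_gte(vae_kl(mu, lv), 0)
  expect_equal(vae_kl(matrix(0, 10, 2), matrix(0, 10, 2)), 0)
})

test_that("AE and VAE training reduces the loss on synthetic images", {
  imgs <- fixture_images(8, seed = 55)
  sub <- imgs[image_labels(imgs) == "left"]
  for (kind in c("ae", "vae")) {
    m <- train_autoencoder(kind, sub, ae_config(width = 4, epochs = 5,
                                                batch_size = 16, seed = 2))
    expect_lt(utils::tail(m$loss_history, 1), m$loss_history[1])
    smp <- sample_autoencoder(m, 10, "left", seed = 3)
    expect_length(smp, 10)
    expect_identical(unique(image_provenance(smp)), kind)
    expect_identical(sample_autoencoder(m, 4, "left", seed = 9),
                     sample_autoencoder(m, 4, "left", seed = 9))
  }
})

test_that("discriminator accuracy drifts toward chance as training balances", {
  imgs <- fixture_images(10, seed = 31)
  sub <- imgs[image_labels(imgs) == "right"]
  drift <- vapply(1:5, function(sd_) {
    cfg <- gan_config(width = 4, epochs = 8, batch_size = 10, seed = sd_)
    st <- train_dcgan(sub, cfg)
    acc_at <- function(state) {
      gen <- sample_generated(state, length(sub), "right", seed = sd_ + 50)
      xr <- image_array(sub) * 2 - 1
      xg <- image_array(gen) * 2 - 1
      sr <- miaug:::net_forward(state$discriminator, xr)$out
      sg <- miaug:::net_forward(state$discriminator, xg)$out
      mean(c(sr > 0.5, sg <= 0.5))
    }
    cfg1 <- cfg; cfg1$epochs <- 1L
    st1 <- train_dcgan(sub, cfg1)
    abs(acc_at(st) - 0.5) - abs(acc_at(st1) - 0.5)
  }, 0)
  expect_lte(stats::median(drift), 0)
})
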