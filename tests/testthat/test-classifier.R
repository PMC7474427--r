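# Classification CNN: architecture, loss, training, prediction contracts.

test_that("CNN layer dimensions follow the compact architecture", {
  net <- build_cnn()
  shp <- miaug:::net_out_shapes(net)
  expect_identical(shp[[1]], c(64L, 64L, 8L))
  expect_identical(shp[[2]], c(32L, 32L, 8L))
  expect_identical(shp[[3]], c(32L, 32L, 8L))
  expect_identical(shp[[4]], c(16L, 16L, 8L))
  expect_identical(shp[[5]], 10L)
  expect_identical(shp[[6]], 2L)
  expect_identical(dim(net$layers[[5]]$W), c(10L, 2048L))
  expect_error(build_cnn(filters = 0), "filters")
})

test_that("softmax output is a probability vector", {
  set.seed(2)
  net <- build_cnn()
  x <- array(runif(64 * 64 * 3 * 5), c(64, 64, 3, 5))
  out <- miaug:::net_forward(net, x)$out
  expect_equal(colSums(out), rep(1, 5), tolerance = 1e-6)
})

test_that("cnn_loss reproduces the printed cross-entropy", {
  expect_lt(cnn_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_equal(cnn_loss(rep(0.5, 8), rep(c(0, 1), 4)), log(2), tolerance = 1e-12)
  set.seed(5)
  p <- runif(50, 0.01, 0.99); y <- rbinom(50, 1, 0.5)
  bf <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(cnn_loss(p, y), bf, tolerance = 1e-10)
  probs <- rbind(1 - p, p)
  expect_equal(cnn_loss(probs, y), bf, tolerance = 1e-10)
})

test_that("training is deterministic and refuses single-class data", {
  imgs <- fixture_images(4, seed = 19)
  cfg <- cnn_config(epochs = 2, filters = 2, dense_units = 4, seed = 6)
  m1 <- train_cnn(imgs, cfg)
  m2 <- train_cnn(imgs, cfg)
  expect_identical(m1$net$layers, m2$net$layers)
  expect_length(m1$loss_history, 2)
  expect_error(train_cnn(imgs[image_labels(imgs) == "left"], cfg),
               "per class")
})

test_that("training drives the loss down on clean synthetic data", {
  imgs <- fixture_images(15, noise = 0.3, seed = 23)
  cfg <- cnn_config(epochs = 8, learning_rate = 0.01, seed = 4)
  m <- train_cnn(imgs, cfg)
  expect_lt(utils::tail(m$loss_history, 1), m$loss_history[1])
})

test_that("the CNN separates two constant-intensity classes perfectly", {
  set.seed(3)
  mk <- function(v, lab) spectrogram_image(
    array(pmin(pmax(v + runif(64 * 64 * 3, -0.02, 0.02), 0), 1),
          c(64, 64, 3)), lab)
  imgs <- c(lapply(rep(0.25, 12), mk, lab = "left"),
            lapply(rep(0.75, 12), mk, lab = "right"))
  m <- train_cnn(imgs, cnn_config(epochs = 20, learning_rate = 0.01, seed = 8))
  pred <- predict_cnn(m, imgs)
  expect_equal(accuracy(pred$labels, image_labels(imgs)), 1.0)
})

test_that("predictions are argmax rows, sum to one, and ignore batch order", {
  imgs <- fixture_images(4, seed = 19)
  m <- train_cnn(imgs, cnn_config(epochs = 2, filters = 2, dense_units = 4,
                                  seed = 6))
  pred <- predict_cnn(m, imgs)
  expect_equal(rowSums(pred$probabilities), rep(1, length(imgs)),
               tolerance = 1e-6)
  expect_identical(pred$labels,
                   m$classes[max.col(pred$probabilities, "first")])
  perm <- rev(seq_along(imgs))
  pred2 <- predict_cnn(m, imgs[perm])
  expect_equal(pred2$probabilities, pred$probabilities[perm, ],
               tolerance = 1e-10)
})

test_that("dropout is active in training mode but not at prediction", {
  imgs <- fixture_images(4, seed = 19)
  m <- train_cnn(imgs, cnn_config(epochs = 1, filters = 2, dense_units = 4,
                                  dropout = 0.5, seed = 6))
  x <- image_array(imgs) * 2 - 1
  e1 <- miaug:::net_forward(m$net, x, training = FALSE)$out
  e2 <- miaug:::net_forward(m$net, x, training = FALSE)$out
  expect_identical(e1, e2)
  set.seed(1); t1 <- miaug:::net_forward(m$net, x, training = TRUE)$out
  set.seed(2); t2 <- miaug:::net_forward(m$net, x, training = TRUE)$out
  expect_false(identical(t1, t2))
})

test_that("CNN gradients pass a numerical check on a tiny slice", {
  set.seed(44)
  net <- miaug:::net_init(list(
    miaug:::layer_conv(2, activation = "tanh"),
    miaug:::layer_maxpool(2),
    miaug:::layer_dense(3, activation = "tanh"),
    miaug:::layer_dense(2, activation = "linear")), c(8, 8, 3), init = "he")
  x <- array(rnorm(8 * 8 * 3 * 3), dim = c(8, 8, 3, 3))
  expect_lt(check_gradients(net, x), 1e-4)
})
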