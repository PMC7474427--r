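# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

# small synthetic image set (both classes), cached per parameter combo
fixture_images <- function(n_per_class = 10, noise = 1.0, seed = 42) {
  key <- sprintf("imgs_%d_%g_%d", n_per_class, noise, seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_config(n_trials_per_class = n_per_class, noise_level = noise,
                      seed = seed)
    .fixtures[[key]] <- trials_to_images(simulate_trials(cfg))
  }
  .fixtures[[key]]
}

# uniform-random pixel image, for contract tests that need arbitrary content
random_image <- function(seed = 1, label = "left") {
  set.seed(seed)
  spectrogram_image(array(stats::runif(64 * 64 * 3), c(64, 64, 3)), label)
}

# generic central-difference gradient checker for miaug nets
check_gradients <- function(net, x, n_per_param = 4, eps = 1e-6) {
  lossfun <- function(net) sum(miaug:::net_forward(net, x, training = TRUE)$out^2)
  fw <- miaug:::net_forward(net, x, training = TRUE)
  gr <- miaug:::net_backward(net, fw$caches, 2 * fw$out)$grads
  worst <- 0
  for (i in seq_along(net$layers)) {
    for (p in names(gr[[i]])) {
      g <- gr[[i]][[p]]
      for (j in sample(length(g), min(n_per_param, length(g)))) {
        n2 <- net; n2$layers[[i]][[p]][j] <- n2$layers[[i]][[p]][j] + eps
        n3 <- net; n3$layers[[i]][[p]][j] <- n3$layers[[i]][[p]][j] - eps
        num <- (lossfun(n2) - lossfun(n3)) / (2 * eps)
        den <- max(abs(num) + abs(g[j]), 1e-4)
        worst <- max(worst, abs(num - g[j]) / den)
      }
    }
  }
  worst
}
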