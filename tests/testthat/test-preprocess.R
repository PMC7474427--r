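make_recording <- function(freqs = c(10), fs = 250, secs = 30, amp = 1,
                           n_events = 4) {
  tt <- (0:(fs * secs - 1)) / fs
  sig <- matrix(rep(rowSums(sapply(freqs, function(f) amp * sin(2 * pi * f * tt))),
                    each = 3), nrow = 3, byrow = FALSE)
  sig <- matrix(sig, nrow = 3)
  ev <- data.frame(sample = seq(fs, by = 5 * fs, length.out = n_events),
                   label = rep(c("left", "right"), length.out = n_events))
  continuous_recording(sig, fs, ev)
}

test_that("band-pass keeps in-band tones and removes out-of-band tones", {
  fs <- 250
  tt <- (0:(fs * 20 - 1)) / fs
  mk <- function(f) {
    sig <- matrix(rep(sin(2 * pi * f * tt), 3), nrow = 3, byrow = TRUE)
    continuous_recording(sig, fs, data.frame(sample = 1L, label = "left"))
  }
  # steady-state amplitude measured away from the edges
  amp_after <- function(f) {
    filt <- bandpass_filter(mk(f), 8, 30, order = 4)
    mid <- (5 * fs):(15 * fs)
    max(abs(filt$signal[1, mid]))
  }
  expect_gte(amp_after(20), 0.9)
  expect_lte(amp_after(2), 0.1)
  z <- mk(10); z$signal[] <- 0
  expect_equal(bandpass_filter(z, 8, 30)$signal, z$signal)
  expect_error(bandpass_filter(mk(10), 8, 130), "fs/2")
})

test_that("epoching yields fs * window samples and copies labels", {
  rec100 <- make_recording(fs = 100, secs = 25)
  tr <- epoch_trials(rec100, 4)
  expect_identical(dim(tr$data)[3], 400L)
  rec250 <- make_recording(fs = 250, secs = 25)
  expect_identical(dim(epoch_trials(rec250, 4)$data)[3], 1000L)
  expect_identical(tr$labels, rec100$events$label)
})

test_that("epoching refuses a marker whose window leaves the recording", {
  rec <- make_recording(fs = 100, secs = 5, n_events = 1)
  rec$events$sample <- ncol(rec$signal)
  expect_error(epoch_trials(rec, 4), "marker 1")
})

test_that("STFT restricts to the requested band with fs/window spacing", {
  x <- numeric(400)
  m0 <- stft_spectrogram(x, 100, 128)
  expect_true(all(m0 == 0))
  expect_identical(nrow(m0), 28L)  # bins ceil(8*128/100) .. floor(30*128/100)
  fr <- attr(m0, "freqs")
  expect_true(all(fr >= 8 & fr <= 30))
  expect_equal(diff(fr)[1], 100 / 128)
  expect_error(stft_spectrogram(numeric(64), 100, 128), "window_size")
  expect_error(stft_spectrogram(x, 100, 128, overlap = 128), "overlap")
})

test_that("STFT peaks at the tone frequency, matching a reference DFT", {
  fs <- 100; w <- 128
  x <- sin(2 * pi * 10 * (0:399) / fs)
  m <- stft_spectrogram(x, fs, w)
  fr <- attr(m, "freqs")
  peak <- fr[apply(m, 2, which.max)]
  expect_true(all(abs(peak - 10) <= fs / w))
  # reference: direct DFT of the first Hann-windowed frame
  win <- 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / (w - 1)))
  seg <- x[1:w] * win
  ref <- vapply(seq_along(fr), function(i) {
    k <- round(fr[i] * w / fs)
    Mod(sum(seg * exp(-2i * pi * k * (0:(w - 1)) / w)))
  }, 0)
  expect_equal(unname(m[, 1]), ref, tolerance = 1e-8)
})

test_that("scaling a trial never decreases STFT magnitudes", {
  set.seed(4)
  x <- rnorm(400)
  m1 <- stft_spectrogram(x, 100, 128)
  m2 <- stft_spectrogram(3 * x, 100, 128)
  expect_true(all(m2 >= m1 - 1e-12))
})

test_that("spectrogram images have the contracted shape and range", {
  tr <- simulate_trials(sim_config(n_trials_per_class = 2, seed = 3))
  img <- build_image(matrix(tr$data[1, , ], nrow = 3), tr$fs,
                     label = tr$labels[1])
  expect_identical(dim(img$pixels), c(64L, 64L, 3L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_identical(img$provenance, "real")
  expect_error(build_image(matrix(0, 2, 400), 100), "3 x samples")
})

test_that("identical channels give a vertically periodic stacked image", {
  set.seed(9)
  ch <- rnorm(400)
  img <- build_image(rbind(ch, ch, ch), 100)
  top <- img$pixels[1:20, , ]
  mid <- img$pixels[22:41, , ]
  expect_lt(mean(abs(top - mid)), 0.1)
})

test_that("an all-zero trial maps to the colormap value at magnitude zero", {
  img <- build_image(matrix(0, 3, 400), 100)
  pal0 <- grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")[1]) / 255
  for (k in 1:3) expect_true(all(abs(img$pixels[, , k] - pal0[k]) < 1e-6))
})

test_that("the image pipeline is deterministic", {
  tr <- simulate_trials(sim_config(n_trials_per_class = 2, seed = 13))
  a <- trials_to_images(tr)
  b <- trials_to_images(tr)
  expect_identical(a, b)
})
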