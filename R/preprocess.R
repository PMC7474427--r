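# Filtering, epoching, and stacked STFT spectrogram-image construction.

#' Construct a continuous EEG recording
#'
#' @param signal `channels x samples` numeric matrix.
#' @param fs sampling rate in Hz (> 0).
#' @param events data frame with columns `sample` (1-based sample index of
#'   each imagery-cue marker) and `label` (class).
#' @param channel_names ordered channel names (default C3, Cz, C4).
#' @return a `continuous_recording`.
#' @export
continuous_recording <- function(signal, fs, events,
                                 channel_names = c("C3", "Cz", "C4")) {
  stopifnot(is.matrix(signal), fs > 0)
  if (nrow(signal) != length(channel_names))
    stop("signal must have one row per channel")
  if (!all(c("sample", "label") %in% names(events)))
    stop("events needs columns 'sample' and 'label'")
  if (any(events$sample < 1 | events$sample > ncol(signal)))
    stop("event sample indices must lie within the recording")
  structure(list(signal = signal, fs = fs, events = events,
                 channel_names = channel_names),
            class = "continuous_recording")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each channel with an order-`order` Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), so the passband gain is ~1 and
#' event latencies are preserved. The motor-imagery pipeline uses 8-30 Hz.
#'
#' @param recording a [continuous_recording()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order (default 4).
#' @return a filtered `continuous_recording` with identical metadata.
#' @export
bandpass_filter <- function(recording, low = 8, high = 30, order = 4) {
  stopifnot(inherits(recording, "continuous_recording"))
  nyq <- recording$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- recording
  for (ch in seq_len(nrow(recording$signal))) {
    out$signal[ch, ] <- signal::filtfilt(bf, recording$signal[ch, ])
  }
  out
}

#' Epoch a continuous recording into trials
#'
#' Cuts a fixed-length window starting at each event marker (the imagery
#' cue) and returns the stacked trials with labels copied from the markers.
#'
#' @param recording a [continuous_recording()].
#' @param window epoch length in seconds (default 4 s).
#' @return a [trial_set()].
#' @export
epoch_trials <- function(recording, window = 4.0) {
  stopifnot(inherits(recording, "continuous_recording"))
  n_samp <- as.integer(round(recording$fs * window))
  n_total <- ncol(recording$signal)
  ev <- recording$events
  for (i in seq_len(nrow(ev))) {
    if (ev$sample[i] + n_samp - 1 > n_total)
      stop(sprintf("epoch for marker %d (sample %d, label %s) extends past the recording",
                   i, ev$sample[i], ev$label[i]))
  }
  data <- array(0, dim = c(nrow(ev), nrow(recording$signal), n_samp))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$sample[i]:(ev$sample[i] + n_samp - 1)
    data[i, , ] <- recording$signal[, idx]
  }
  trial_set(data, ev$label, recording$fs, recording$channel_names)
}

#' Short-time Fourier transform magnitude of one channel
#'
#' Hann-tapered sliding-window Fourier magnitudes restricted to a frequency
#' band. Frames advance by `window_size - overlap` samples; the trial tail
#' is zero-padded so every sample is covered. Frequency-bin spacing is
#' `fs / window_size`; retained bins are the integer bins `k` with
#' `low <= k * fs / window_size <= high`.
#'
#' @param x numeric vector, one channel of one trial.
#' @param fs sampling rate in Hz.
#' @param window_size STFT window length in samples (128 at 100 Hz, 256 at
#'   250 Hz in the reference protocol).
#' @param overlap samples shared by consecutive windows; default 50%.
#' @param band retained frequency interval in Hz (default 8-30).
#' @return non-negative `frequency x time` magnitude matrix with
#'   attributes `freqs` (Hz) and `times` (s, frame centers).
#' @export
stft_spectrogram <- function(x, fs, window_size, overlap = window_size %/% 2,
                             band = c(8, 30)) {
  n <- length(x)
  if (window_size > n) stop("window_size must not exceed the trial length")
  if (overlap < 0 || overlap >= window_size)
    stop("overlap must satisfy 0 <= overlap < window_size")
  hop <- window_size - overlap
  n_frames <- max(1L, as.integer(ceiling((n - overlap) / hop)))
  pad_len <- (n_frames - 1L) * hop + window_size
  xp <- c(x, numeric(pad_len - n))
  win <- 0.5 * (1 - cos(2 * pi * (0:(window_size - 1)) / (window_size - 1)))
  frames <- vapply(seq_len(n_frames), function(j) {
    xp[((j - 1L) * hop + 1L):((j - 1L) * hop + window_size)] * win
  }, numeric(window_size))
  spec <- Mod(stats::mvfft(frames))
  k <- 0:(window_size - 1)
  freqs <- k * fs / window_size
  keep <- which(freqs >= band[1] & freqs <= band[2] & k <= window_size / 2)
  mag <- spec[keep, , drop = FALSE]
  attr(mag, "freqs") <- freqs[keep]
  attr(mag, "times") <- ((seq_len(n_frames) - 1) * hop + window_size / 2) / fs
  mag
}

# map magnitudes in [0,1] through a colormap to an (H, W, 3) RGB array
apply_colormap <- function(v, colormap = "viridis") {
  pal <- grDevices::hcl.colors(256, colormap)
  rgbm <- grDevices::col2rgb(pal) / 255
  idx <- pmin(pmax(floor(v * 255) + 1L, 1L), 256L)
  out <- array(0, dim = c(nrow(v), ncol(v), 3))
  for (k in 1:3) out[, , k] <- matrix(rgbm[k, idx], nrow(v), ncol(v))
  out
}

#' Build the stacked spectrogram image of one trial
#'
#' Computes the STFT magnitude of each of the three channels, stacks the
#' per-channel matrices vertically in channel order (C3 on top, then Cz,
#' then C4, so neighboring rows stay informative), takes log-magnitudes
#' (`log1p`), min-max scales the stacked matrix to `[0, 1]` per image, maps
#' it through a perceptually uniform colormap to three planes, and
#' bilinearly resizes to 64 x 64.
#'
#' @param trial `3 x samples` numeric matrix with rows ordered C3, Cz, C4.
#' @param fs sampling rate in Hz.
#' @param window_size,overlap,band STFT parameters, see
#'   [stft_spectrogram()].
#' @param colormap palette name understood by `grDevices::hcl.colors`.
#' @param label,subject_id metadata for the resulting image.
#' @return a [spectrogram_image()] with provenance `"real"`.
#' @export
build_image <- function(trial, fs, window_size = 128,
                        overlap = window_size %/% 2, band = c(8, 30),
                        colormap = "viridis", label = "left",
                        subject_id = NA_character_) {
  if (!is.matrix(trial) || nrow(trial) != 3)
    stop("trial must be a 3 x samples matrix (channels C3, Cz, C4)")
  mags <- lapply(seq_len(3), function(ch)
    stft_spectrogram(trial[ch, ], fs, window_size, overlap, band))
  stacked <- do.call(rbind, mags)
  v <- log1p(stacked)
  rng <- range(v)
  v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  big <- apply_colormap(v, colormap)
  img <- EBImage::Image(big, colormode = "Color")
  small <- EBImage::resize(img, w = 64, h = 64)
  px <- pmin(pmax(as.numeric(EBImage::imageData(small)), 0), 1)
  dim(px) <- c(64L, 64L, 3L)
  spectrogram_image(px, label, "real", subject_id)
}

#' Convert every trial of a trial set to a spectrogram image
#'
#' The STFT window defaults to 128 samples below 125 Hz and 256 samples at
#' higher rates, matching the 100 Hz / 250 Hz dataset conventions.
#'
#' @param trials a [trial_set()].
#' @param window_size,overlap,band,colormap see [build_image()].
#' @param subject_id subject identifier attached to every image.
#' @return list of [spectrogram_image()].
#' @export
trials_to_images <- function(trials, window_size = NULL,
                             overlap = NULL, band = c(8, 30),
                             colormap = "viridis",
                             subject_id = NA_character_) {
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(window_size)) window_size <- if (trials$fs <= 125) 128L else 256L
  if (is.null(overlap)) overlap <- window_size %/% 2L
  lapply(seq_len(dim(trials$data)[1]), function(i) {
    build_image(matrix(trials$data[i, , ], nrow = dim(trials$data)[2]),
                trials$fs, window_size, overlap, band, colormap,
                label = trials$labels[i], subject_id = subject_id)
  })
}
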