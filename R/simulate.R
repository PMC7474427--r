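# Synthetic two-class motor-imagery EEG with ERD/ERS band-power structure.

#' Simulation configuration for synthetic motor-imagery EEG
#'
#' Describes a two-class (left/right hand imagery) recording over the
#' sensorimotor electrodes C3, Cz, C4. Each trial is 1/f background noise
#' plus mu (8-12 Hz) and beta (18-26 Hz) oscillations whose amplitudes are
#' modulated by class: imagery of one hand attenuates the oscillations at
#' the contralateral electrode (event-related desynchronization, ERD) and
#' enhances them at the ipsilateral electrode (event-related
#' synchronization, ERS). Right-hand imagery attenuates C3 (left motor
#' cortex); left-hand imagery attenuates C4. Cz is never modulated. This
#' laterality convention is fixed.
#'
#' @param n_trials_per_class number of trials per class (>= 1).
#' @param fs sampling rate in Hz (typically 100 or 250).
#' @param duration trial length in seconds; `fs * duration` must be an
#'   integer sample count. Default 4 s imagery epochs.
#' @param channels ordered channel names; fixed default `C3, Cz, C4`.
#' @param erd_depth fractional mu/beta amplitude reduction at the
#'   contralateral electrode, in `[0, 1]`.
#' @param ers_gain fractional amplitude increase at the ipsilateral
#'   electrode, >= 0.
#' @param noise_level amplitude of the 1/f background noise, >= 0.
#' @param mu_freq,beta_freq oscillation frequencies in Hz.
#' @param mu_amp,beta_amp baseline oscillation amplitudes.
#' @param amp_jitter half-width of the uniform multiplicative
#'   trial-to-trial amplitude jitter.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   trial sets.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_trials_per_class = 100L, fs = 100, duration = 4.0,
                       channels = c("C3", "Cz", "C4"),
                       erd_depth = 0.5, ers_gain = 0.2, noise_level = 1.0,
                       mu_freq = 10, beta_freq = 22,
                       mu_amp = 1.0, beta_amp = 0.5,
                       amp_jitter = 0.1, seed = 1L) {
  if (erd_depth < 0 || erd_depth > 1)
    stop("erd_depth must lie in [0, 1]")
  n_samp <- fs * duration
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("fs * duration must be an integer sample count")
  if (n_trials_per_class < 1) stop("n_trials_per_class must be >= 1")
  if (ers_gain < 0) stop("ers_gain must be >= 0")
  if (noise_level < 0) stop("noise_level must be >= 0")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 fs = fs, duration = duration, channels = channels,
                 erd_depth = erd_depth, ers_gain = ers_gain,
                 noise_level = noise_level, mu_freq = mu_freq,
                 beta_freq = beta_freq, mu_amp = mu_amp,
                 beta_amp = beta_amp, amp_jitter = amp_jitter,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct an epoched trial set
#'
#' @param data `trials x channels x samples` numeric array.
#' @param labels per-trial class labels in `{left, right}`.
#' @param fs sampling rate in Hz.
#' @param channel_names ordered channel names.
#' @return a `trial_set`.
#' @export
trial_set <- function(data, labels, fs, channel_names) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(labels) != dim(data)[1])
    stop("labels length must equal trial count")
  if (dim(data)[2] != length(channel_names))
    stop("channel dimension must match channel_names")
  structure(list(data = data, labels = as.character(labels), fs = fs,
                 channel_names = channel_names),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  print(table(x$labels))
  invisible(x)
}

# 1/f-amplitude-shaped noise: white Gaussian noise spectrally reweighted by
# f^(-1/2) (power ~ 1/f), unit variance before scaling.
one_over_f_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  shape <- ifelse(f > 0, f^(-0.5), 0)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate two-class motor-imagery trials
#'
#' Generates `2 * n_trials_per_class` balanced trials. For class `"right"`,
#' the mu/beta oscillation amplitude at C3 is scaled by `(1 - erd_depth)`
#' and at C4 by `(1 + ers_gain)`; mirrored for class `"left"`; Cz is left
#' unmodulated. Oscillation phases are drawn uniformly per trial and channel
#' so trials are not phase-locked, and modulation applies over the whole
#' epoch. Reproducible bit-for-bit for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return a [trial_set()] with trials ordered left-class first.
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_samp <- as.integer(round(config$fs * config$duration))
  n_tr <- 2L * config$n_trials_per_class
  labels <- rep(c("left", "right"), each = config$n_trials_per_class)
  tt <- (0:(n_samp - 1)) / config$fs
  data <- array(0, dim = c(n_tr, length(config$channels), n_samp))
  for (i in seq_len(n_tr)) {
    lab <- labels[i]
    for (ch in seq_along(config$channels)) {
      chn <- config$channels[ch]
      mod <- 1
      if (chn == "C3") {
        mod <- if (lab == "right") 1 - config$erd_depth else 1 + config$ers_gain
      } else if (chn == "C4") {
        mod <- if (lab == "left") 1 - config$erd_depth else 1 + config$ers_gain
      }
      jit <- 1 + stats::runif(2, -config$amp_jitter, config$amp_jitter)
      ph <- stats::runif(2, 0, 2 * pi)
      osc <- mod * (config$mu_amp * jit[1] * sin(2 * pi * config$mu_freq * tt + ph[1]) +
                    config$beta_amp * jit[2] * sin(2 * pi * config$beta_freq * tt + ph[2]))
      bg <- if (config$noise_level > 0)
        config$noise_level * one_over_f_noise(n_samp, config$fs) else 0
      data[i, ch, ] <- osc + bg
    }
  }
  trial_set(data, labels, config$fs, config$channels)
}

#' Per-trial band power
#'
#' Periodogram-based power of one channel in a frequency band, in
#' mean-square units: summing over all bands recovers the mean squared
#' signal (Parseval), so a unit-amplitude sinusoid inside the band yields
#' 0.5.
#'
#' @param trials a [trial_set()].
#' @param band numeric length-2 interval in Hz, inside `(0, fs/2)`.
#' @param channel channel name.
#' @return non-negative numeric vector, one value per trial.
#' @export
bandpower <- function(trials, band, channel) {
  stopifnot(inherits(trials, "trial_set"), length(band) == 2)
  if (band[1] <= 0 || band[2] >= trials$fs / 2 || band[1] >= band[2])
    stop("band must lie within (0, fs/2)")
  ch <- match(channel, trials$channel_names)
  if (is.na(ch)) stop("unknown channel name: ", channel)
  n <- dim(trials$data)[3]
  freqs <- (0:(n - 1)) * trials$fs / n
  sel <- freqs >= band[1] & freqs <= band[2] & freqs <= trials$fs / 2
  apply(trials$data[, ch, , drop = FALSE], 1, function(x) {
    p <- Mod(stats::fft(as.numeric(x)))^2 / n^2
    2 * sum(p[sel])
  })
}

#' Write a trial set to disk
#'
#' The array goes into R's compressed array container (RDS); sampling rate,
#' labels, and channel names go into a JSON sidecar `<path>.json`.
#' @param trials a [trial_set()].
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  saveRDS(trials$data, path)
  jsonlite::write_json(list(fs = trials$fs, labels = trials$labels,
                            channel_names = trials$channel_names),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read a trial set written by [write_trials()]
#' @param path file path.
#' @export
read_trials <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trial_set(readRDS(path), meta$labels, meta$fs, meta$channel_names)
}
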