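# Non-generative augmenters: geometric transformations and noise addition.

#' Augmentation configuration for the classical augmenters
#'
#' @param method one of `"gt_rotate"`, `"gt_shift"`, `"gt_color"`, `"na"`.
#' @param shift_max maximum absolute translation in pixels (< 64).
#' @param noise_scale multiplier of the uniform perturbation in the
#'   noise-addition rule `x~ = x + random(-0.5, 0.5) * noise_scale`, >= 0.
#' @param brightness half-width of the additive brightness jitter.
#' @param contrast half-width of the multiplicative contrast jitter.
#' @param na_distribution `"uniform"` (the printed rule) or `"gaussian"`
#'   (matched variance).
#' @param rotate_mode `"planar"` (180 degree rotation) or `"vflip"`.
#' @param seed integer RNG seed.
#' @return an `augment_config` list.
#' @export
augment_config <- function(method = c("gt_rotate", "gt_shift", "gt_color", "na"),
                           shift_max = 8L, noise_scale = 0.2,
                           brightness = 0.1, contrast = 0.1,
                           na_distribution = c("uniform", "gaussian"),
                           rotate_mode = c("planar", "vflip"), seed = 1L) {
  method <- match.arg(method)
  if (shift_max >= 64) stop("shift_max must be < 64")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(method = method, shift_max = as.integer(shift_max),
                 noise_scale = noise_scale, brightness = brightness,
                 contrast = contrast,
                 na_distribution = match.arg(na_distribution),
                 rotate_mode = match.arg(rotate_mode),
                 seed = as.integer(seed)),
            class = "augment_config")
}

new_augmented <- function(image, pixels, provenance) {
  spectrogram_image(pixels, image$label, provenance, image$subject_id)
}

#' Rotate a spectrogram image by 180 degrees
#'
#' Planar 180 degree rotation: input pixel `(r, c, k)` lands at
#' `(63 - r, 63 - c, k)` (0-based). Applying it twice is the identity.
#' `mode = "vflip"` instead flips vertically (also an involution).
#'
#' @param image a [spectrogram_image()].
#' @param mode `"planar"` or `"vflip"`.
#' @return augmented image with provenance `"gt"`.
#' @export
gt_rotate <- function(image, mode = c("planar", "vflip")) {
  mode <- match.arg(mode)
  px <- if (mode == "planar") image$pixels[64:1, 64:1, , drop = FALSE]
        else image$pixels[64:1, , , drop = FALSE]
  dim(px) <- c(64L, 64L, 3L)
  new_augmented(image, px, "gt")
}

#' Translate a spectrogram image, filling vacated pixels with noise
#'
#' Shifts the content by `dx` columns (positive = right) and `dy` rows
#' (positive = down); vacated rows/columns are filled with uniform random
#' values in `[0, 1]`.
#'
#' @param image a [spectrogram_image()].
#' @param dx,dy integer shifts with `|dx|, |dy| <= shift_max`.
#' @param shift_max maximum permitted shift.
#' @return augmented image with provenance `"gt"`.
#' @export
gt_shift <- function(image, dx, dy, shift_max = 8L) {
  if (abs(dx) > shift_max || abs(dy) > shift_max)
    stop("|dx| and |dy| must not exceed shift_max")
  px <- array(stats::runif(64 * 64 * 3), dim = c(64L, 64L, 3L))
  src_r <- seq_len(64) - dy
  src_c <- seq_len(64) - dx
  ok_r <- which(src_r >= 1 & src_r <= 64)
  ok_c <- which(src_c >= 1 & src_c <= 64)
  px[ok_r, ok_c, ] <- image$pixels[src_r[ok_r], src_c[ok_c], , drop = FALSE]
  new_augmented(image, px, "gt")
}

#' Color-space jitter of a spectrogram image
#'
#' Perturbs contrast about mid-gray and brightness:
#' `out = clip((x - 0.5) * contrast_factor + 0.5 + brightness_offset)`.
#' When the offsets are not given they are drawn uniformly within the
#' configured half-widths; zero-width ranges give the identity.
#'
#' @param image a [spectrogram_image()].
#' @param brightness,contrast jitter half-widths.
#' @param brightness_offset,contrast_factor optional explicit values
#'   overriding the random draw.
#' @return augmented image with provenance `"gt"`.
#' @export
gt_color <- function(image, brightness = 0.1, contrast = 0.1,
                     brightness_offset = NULL, contrast_factor = NULL) {
  if (is.null(brightness_offset))
    brightness_offset <- stats::runif(1, -brightness, brightness)
  if (is.null(contrast_factor))
    contrast_factor <- stats::runif(1, 1 - contrast, 1 + contrast)
  px <- (image$pixels - 0.5) * contrast_factor + 0.5 + brightness_offset
  px <- pmin(pmax(px, 0), 1)
  new_augmented(image, px, "gt")
}

#' Noise-addition augmentation
#'
#' Implements the perturbation rule `x~ = x + random(-0.5, 0.5) *
#' noise_scale` per pixel (uniform draw as printed; a variance-matched
#' Gaussian is available), then clips to `[0, 1]`.
#'
#' @param image a [spectrogram_image()].
#' @param noise_scale perturbation multiplier, >= 0.
#' @param distribution `"uniform"` or `"gaussian"`.
#' @return augmented image with provenance `"na"`.
#' @export
noise_addition <- function(image, noise_scale = 0.2,
                           distribution = c("uniform", "gaussian")) {
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  distribution <- match.arg(distribution)
  n <- length(image$pixels)
  u <- if (distribution == "uniform") stats::runif(n, -0.5, 0.5)
       else stats::rnorm(n, 0, sqrt(1 / 12))
  px <- image$pixels + u * noise_scale
  px <- pmin(pmax(px, 0), 1)
  dim(px) <- c(64L, 64L, 3L)
  new_augmented(image, px, "na")
}

#' Generate a batch of classically augmented images
#'
#' Cycles over the input images, applying the configured augmenter (for
#' `method = "gt"` a rotation, shift, or color jitter is chosen at random
#' per copy) until `n_out` images are produced. Labels and subject ids are
#' inherited; only provenance changes.
#'
#' @param images list of [spectrogram_image()].
#' @param method `"gt"` or `"na"`.
#' @param n_out number of augmented images to generate.
#' @param config an [augment_config()] supplying operator parameters.
#' @param seed integer RNG seed.
#' @return list of augmented images.
#' @export
augment_images <- function(images, method = c("gt", "na"), n_out,
                           config = augment_config(), seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  out <- vector("list", n_out)
  src <- rep_len(seq_along(images), n_out)
  for (i in seq_len(n_out)) {
    im <- images[[src[i]]]
    out[[i]] <- if (method == "na") {
      noise_addition(im, config$noise_scale, config$na_distribution)
    } else {
      switch(sample(c("rot", "shift", "color"), 1),
        rot = gt_rotate(im, config$rotate_mode),
        shift = gt_shift(im, sample(-config$shift_max:config$shift_max, 1),
                         sample(-config$shift_max:config$shift_max, 1),
                         config$shift_max),
        color = gt_color(im, config$brightness, config$contrast))
    }
  }
  out
}
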