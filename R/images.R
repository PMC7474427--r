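# Spectrogram-image container and image-set helpers.

PROVENANCE_LEVELS <- c("real", "generated", "gt", "na", "ae", "vae", "dcgan")
CLASS_LEVELS <- c("left", "right")

#' Construct a spectrogram image
#'
#' A 64 x 64 x 3 image in `[0, 1]` encoding the vertically stacked C3/Cz/C4
#' time-frequency energy of one motor-imagery trial, together with its class
#' label and a provenance flag recording whether the image came from real
#' data or from one of the augmentation strategies.
#'
#' @param pixels numeric array of dimension `c(64, 64, 3)` with values in
#'   `[0, 1]`.
#' @param label class label, `"left"` or `"right"`.
#' @param provenance one of `"real"`, `"generated"`, `"gt"`, `"na"`, `"ae"`,
#'   `"vae"`, `"dcgan"`.
#' @param subject_id optional subject identifier.
#' @return an object of class `spectrogram_image`.
#' @export
spectrogram_image <- function(pixels, label, provenance = "real",
                              subject_id = NA_character_) {
  if (!is.array(pixels) || !identical(dim(pixels), c(64L, 64L, 3L)))
    stop("pixels must be a 64 x 64 x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]")
  label <- match.arg(label, CLASS_LEVELS)
  provenance <- match.arg(provenance, PROVENANCE_LEVELS)
  structure(list(pixels = pixels, label = label, provenance = provenance,
                 subject_id = subject_id),
            class = "spectrogram_image")
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf("<spectrogram_image> label=%s provenance=%s subject=%s\n",
              x$label, x$provenance, x$subject_id))
  invisible(x)
}

#' Stack a list of spectrogram images into a batch array
#'
#' @param images list of `spectrogram_image`.
#' @return `(64, 64, 3, n)` array.
#' @export
image_array <- function(images) {
  stopifnot(length(images) > 0)
  arr <- array(0, dim = c(64, 64, 3, length(images)))
  for (i in seq_along(images)) arr[, , , i] <- images[[i]]$pixels
  arr
}

#' Extract labels from an image set
#' @param images list of `spectrogram_image`.
#' @export
image_labels <- function(images) vapply(images, `[[`, character(1), "label")

#' Extract provenance flags from an image set
#' @param images list of `spectrogram_image`.
#' @export
image_provenance <- function(images) vapply(images, `[[`, character(1), "provenance")

#' Convert a batch array back to a list of spectrogram images
#' @param arr `(64, 64, 3, n)` array in `[0, 1]`.
#' @param labels character vector of class labels (length n or 1).
#' @param provenance single provenance flag.
#' @param subject_id subject identifier.
#' @export
array_to_images <- function(arr, labels, provenance, subject_id = NA_character_) {
  n <- dim(arr)[4]
  labels <- rep_len(labels, n)
  lapply(seq_len(n), function(i)
    spectrogram_image(arr[, , , i, drop = TRUE], labels[i], provenance, subject_id))
}

#' Write an image set to disk
#'
#' Pixels go into R's compressed array container (RDS); labels, provenance,
#' and subject ids go into a JSON sidecar `<path>.json`.
#' @param images list of `spectrogram_image`.
#' @param path output file path.
#' @export
write_images <- function(images, path) {
  saveRDS(image_array(images), path)
  jsonlite::write_json(
    list(labels = image_labels(images),
         provenance = image_provenance(images),
         subject_id = vapply(images, `[[`, character(1), "subject_id")),
    paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read an image set written by [write_images()]
#' @param path file path.
#' @export
read_images <- function(path) {
  arr <- readRDS(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- vector("list", dim(arr)[4])
  for (i in seq_along(out)) {
    out[[i]] <- spectrogram_image(arr[, , , i, drop = TRUE], meta$labels[i],
                                  meta$provenance[i], meta$subject_id[i])
  }
  out
}

#' Write an image as a PNG file for visual inspection
#' @param image a `spectrogram_image`.
#' @param path output PNG path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image$pixels, path)
  invisible(path)
}
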