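# Generated-data quality (Frechet distance) and classification metrics.

#' Extract feature embeddings from spectrogram images
#'
#' Embeds each image as a feature vector for Frechet-distance estimation.
#' The default `"flatten-pca"` embedder flattens the pixels and projects
#' onto the leading principal components of a reference set (normally the
#' real images), so it is deterministic and needs no external weights.
#' `"small-cnn"` uses the penultimate dense activations of a fixed-seed
#' random-weights copy of the package CNN. `"pretrained-inception"` is the
#' classical choice; it needs user-supplied network weights, which this
#' package does not bundle, so selecting it without an `embed_fun` raises
#' an error.
#'
#' @param images list of [spectrogram_image()].
#' @param embedder `"flatten-pca"`, `"small-cnn"`, or
#'   `"pretrained-inception"`.
#' @param fit_images reference images the embedder is fit on (PCA basis);
#'   defaults to `images`. Pass the real set when embedding generated data.
#' @param dim embedding dimension for `"flatten-pca"` (default 64, capped
#'   by the reference sample size).
#' @param embed_fun optional function `images -> n x d matrix` implementing
#'   a custom embedder (used for `"pretrained-inception"`).
#' @return a `feature_embedding`: list with `vectors` (n x d matrix) and
#'   `embedder_id`.
#' @export
extract_features <- function(images, embedder = c("flatten-pca", "small-cnn",
                                                  "pretrained-inception"),
                             fit_images = images, dim = 64L,
                             embed_fun = NULL) {
  if (length(images) == 0) stop("image set must be non-empty")
  embedder <- match.arg(embedder)
  flat <- function(imgs) t(vapply(imgs, function(im) as.numeric(im$pixels),
                                  numeric(64 * 64 * 3)))
  if (embedder == "flatten-pca") {
    ref <- flat(fit_images)
    d <- min(dim, nrow(ref) - 1L, ncol(ref))
    pc <- stats::prcomp(ref, rank. = d, center = TRUE, scale. = FALSE)
    vec <- scale(flat(images), center = pc$center, scale = FALSE) %*% pc$rotation
  } else if (embedder == "small-cnn") {
    net <- withr::with_seed(20200448L, build_cnn())
    arr <- image_array(images) * 2 - 1
    # activations of the first dense layer (pre-softmax features)
    fw <- net_forward(net, arr, training = FALSE)
    vec <- t(fw$caches[[length(net$layers) - 1L]]$a)
  } else {
    if (is.null(embed_fun))
      stop("the pretrained-inception embedder requires user-supplied ",
           "weights via embed_fun; no pretrained network is bundled")
    vec <- embed_fun(images)
  }
  if (any(!is.finite(vec))) stop("non-finite feature values")
  structure(list(vectors = unname(as.matrix(vec)), embedder_id = embedder),
            class = "feature_embedding")
}

#' Frechet distance between two feature embeddings
#'
#' Fits a Gaussian to each embedding and computes
#' `||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})`, the
#' Wasserstein-2 distance between the two Gaussians (the Frechet inception
#' distance when the embedder is an Inception network). Covariances use the
#' unbiased estimator with a small diagonal jitter; the matrix square root
#' is computed through the symmetric form
#' `(S_r^{1/2} S_g S_r^{1/2})^{1/2}` by eigendecomposition.
#'
#' @param real,generated `feature_embedding` objects of equal dimension,
#'   each with at least 2 vectors.
#' @param jitter diagonal stabilizer added to both covariances.
#' @return an `fid_result`: list with `value`, `mu_r`, `mu_g`, `sigma_r`,
#'   `sigma_g`, `n_real`, `n_generated`.
#' @export
frechet_distance <- function(real, generated, jitter = 1e-6) {
  stopifnot(inherits(real, "feature_embedding"),
            inherits(generated, "feature_embedding"))
  A <- real$vectors; B <- generated$vectors
  if (ncol(A) != ncol(B)) stop("embedding dimensions differ")
  if (nrow(A) < 2 || nrow(B) < 2) stop("need at least 2 vectors per set")
  if (any(!is.finite(A)) || any(!is.finite(B))) stop("non-finite features")
  mu_r <- colMeans(A); mu_g <- colMeans(B)
  S_r <- stats::cov(A) + diag(jitter, ncol(A))
  S_g <- stats::cov(B) + diag(jitter, ncol(B))
  er <- eigen((S_r + t(S_r)) / 2, symmetric = TRUE)
  sq_r <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  M <- sq_r %*% S_g %*% sq_r
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_cross <- sum(sqrt(pmax(ev, 0)))
  value <- sum((mu_r - mu_g)^2) + sum(diag(S_r)) + sum(diag(S_g)) - 2 * tr_cross
  structure(list(value = value, mu_r = mu_r, mu_g = mu_g,
                 sigma_r = S_r, sigma_g = S_g,
                 n_real = nrow(A), n_generated = nrow(B)),
            class = "fid_result")
}

#' @export
print.fid_result <- function(x, ...) {
  cat(sprintf("<fid_result> value=%.4f (n_real=%d, n_generated=%d, d=%d)\n",
              x$value, x$n_real, x$n_generated, length(x$mu_r)))
  invisible(x)
}

#' Frechet distance between real and generated image sets
#'
#' Convenience wrapper: fits the embedder on the real images and applies it
#' to both sets before calling [frechet_distance()].
#'
#' @param real_images,gen_images lists of [spectrogram_image()].
#' @param embedder,dim see [extract_features()].
#' @return an `fid_result`.
#' @export
fid_images <- function(real_images, gen_images, embedder = "flatten-pca",
                       dim = 64L) {
  fr <- extract_features(real_images, embedder, fit_images = real_images,
                         dim = dim)
  fg <- extract_features(gen_images, embedder, fit_images = real_images,
                         dim = dim)
  frechet_distance(fr, fg)
}

#' Classification accuracy
#' @param predicted,true equal-length label vectors.
#' @return fraction of matches in `[0, 1]`.
#' @export
accuracy <- function(predicted, true) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(true)) stop("length mismatch")
  mean(predicted == true)
}

#' Chance-corrected kappa
#'
#' Two forms are exposed: `formula = "cohen"` (default) is Cohen's
#' `(accuracy - random) / (1 - random)`; `formula = "paper"` is the
#' alternative normalization `(accuracy - random) / random` sometimes used
#' in the motor-imagery literature. `random` is the chance level (0.5 for
#' balanced two-class data).
#'
#' @param accuracy observed accuracy.
#' @param random chance accuracy, in `(0, 1)`.
#' @param formula `"cohen"` or `"paper"`.
#' @export
kappa_score <- function(accuracy, random = 0.5, formula = c("cohen", "paper")) {
  formula <- match.arg(formula)
  if (random <= 0 || random >= 1) stop("random must lie in (0, 1)")
  if (formula == "cohen") (accuracy - random) / (1 - random)
  else (accuracy - random) / random
}

#' Paired two-sided t-test on per-fold scores
#'
#' @param a,b equal-length numeric vectors (length >= 2) of paired scores.
#' @return list with `statistic`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must have equal length >= 2")
  d <- a - b
  if (stats::sd(d) < 1e-12)
    stop("degenerate input: zero variance of paired differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}

#' Classical one-way ANOVA over groups of scores
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (all(vapply(groups, stats::sd, 1) < 1e-12))
    stop("degenerate input: zero within-group variance")
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = ft$p.value,
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
}
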