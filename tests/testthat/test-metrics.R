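# Frechet distance, accuracy/kappa, and significance-test wrappers.

embed_of <- function(mat) structure(list(vectors = mat, embedder_id = "test"),
                                    class = "feature_embedding")

# brute-force Frechet distance: matrix square root of the (non-symmetric)
# product via eigendecomposition, mirroring the closed formula directly
brute_frechet <- function(A, B, jitter = 1e-6) {
  mu1 <- colMeans(A); mu2 <- colMeans(B)
  S1 <- stats::cov(A) + diag(jitter, ncol(A))
  S2 <- stats::cov(B) + diag(jitter, ncol(B))
  P <- S1 %*% S2
  e <- eigen(P)
  sq <- Re(e$vectors %*% diag(sqrt(as.complex(e$values)), ncol(P)) %*%
             solve(e$vectors))
  sum((mu1 - mu2)^2) + sum(diag(S1 + S2 - 2 * sq))
}

test_that("feature extraction is deterministic with one vector per image", {
  imgs <- fixture_images(5, seed = 61)
  f1 <- extract_features(imgs, "flatten-pca", dim = 6)
  f2 <- extract_features(imgs, "flatten-pca", dim = 6)
  expect_identical(f1, f2)
  expect_identical(nrow(f1$vectors), length(imgs))
  f3 <- extract_features(imgs, "small-cnn")
  expect_identical(nrow(f3$vectors), length(imgs))
  expect_identical(extract_features(imgs, "small-cnn")$vectors, f3$vectors)
  expect_error(extract_features(imgs, "pretrained-inception"), "embed_fun")
  expect_error(extract_features(list(), "flatten-pca"), "non-empty")
})

test_that("PCA concentrates a rank-1 image set on the first component", {
  base <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  imgs <- lapply(seq(0.2, 1, length.out = 8), function(s)
    spectrogram_image(base * s, "left"))
  f <- extract_features(imgs, "flatten-pca", dim = 4)
  v <- apply(f$vectors, 2, stats::var)
  expect_gt(v[1] / sum(v), 0.999)
})

test_that("Frechet distance reproduces the univariate closed form", {
  # samples with exact moments: mean 0/1, unit sample variance
  a <- embed_of(matrix(c(-1, 0, 1), ncol = 1))
  b <- embed_of(matrix(c(0, 1, 2), ncol = 1))
  # closed form (mu1-mu2)^2 + s1^2 + s2^2 - 2 s1 s2 = 1
  expect_equal(frechet_distance(a, b)$value, 1.0, tolerance = 1e-5)
})

test_that("Frechet distance is zero on identical sets and symmetric", {
  set.seed(9)
  A <- matrix(rnorm(60), 20, 3)
  B <- matrix(rnorm(60, 1), 20, 3)
  expect_lt(abs(frechet_distance(embed_of(A), embed_of(A))$value), 1e-6)
  d1 <- frechet_distance(embed_of(A), embed_of(B))$value
  d2 <- frechet_distance(embed_of(B), embed_of(A))$value
  expect_lt(abs(d1 - d2), 1e-8)
  expect_gte(d1, 0)
  expect_error(frechet_distance(embed_of(A), embed_of(matrix(0, 5, 2))),
               "dimensions")
})

test_that("Frechet distance matches a brute-force square root on d <= 3", {
  set.seed(10)
  for (d in 1:3) {
    A <- matrix(rnorm(30 * d), 30, d)
    B <- matrix(rnorm(30 * d, 0.5, 1.3), 30, d)
    expect_equal(frechet_distance(embed_of(A), embed_of(B))$value,
                 brute_frechet(A, B), tolerance = 1e-8)
  }
})

test_that("real splits are closer to each other than noise is", {
  imgs <- fixture_images(12, seed = 71)
  a <- imgs[seq(1, 24, 2)]; b <- imgs[seq(2, 24, 2)]
  set.seed(3)
  noise <- lapply(1:12, function(i)
    spectrogram_image(array(stats::runif(64 * 64 * 3), c(64, 64, 3)), "left"))
  f_ab <- fid_images(b, a, dim = 8)$value
  f_nb <- fid_images(b, noise, dim = 8)$value
  expect_lt(f_ab, f_nb)
})

test_that("accuracy and kappa behave per their formulas", {
  expect_equal(accuracy(c("l", "r"), c("l", "r")), 1.0)
  expect_equal(accuracy(c("l", "r"), c("r", "l")), 0.0)
  expect_equal(accuracy(c("l", "l", "r", "r"), c("l", "l", "r", "l")), 0.75)
  expect_error(accuracy(character(0), character(0)), "empty")
  expect_equal(kappa_score(0.5, 0.5, "cohen"), 0)
  expect_equal(kappa_score(0.5, 0.5, "paper"), 0)
  expect_equal(kappa_score(0.75, 0.5, "paper"), 0.5)
  expect_equal(kappa_score(1.0, 0.5, "cohen"), 1.0)
  expect_error(kappa_score(0.8, 0), "random")
  # strictly increasing in accuracy for both forms
  accs <- seq(0.1, 0.9, 0.1)
  expect_true(all(diff(kappa_score(accs, 0.5, "cohen")) > 0))
  expect_true(all(diff(kappa_score(accs, 0.5, "paper")) > 0))
})

test_that("paired t-test matches a hand computation and flags degeneracy", {
  set.seed(11)
  a <- rnorm(10, 0.8, 0.05)
  b <- a + 0.03 + rnorm(10, 0, 0.01)
  res <- paired_ttest(a, b)
  d <- a - b
  t_hand <- mean(d) / (stats::sd(d) / sqrt(10))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_lt(res$statistic, 0)  # b is larger, so the statistic is negative
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "degenerate")
  expect_error(paired_ttest(1, 2), "length")
})

test_that("one-way ANOVA equals the squared pooled t for two groups", {
  set.seed(12)
  g1 <- rnorm(12); g2 <- rnorm(12, 0.4)
  res <- one_way_anova(list(g1, g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$p, tt$p.value, tolerance = 1e-8)
  expect_error(one_way_anova(list(g1)), "2 groups")
  expect_error(one_way_anova(list(c(1, 1, 1), c(2, 2, 2))), "degenerate")
})
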