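test_that("column scaling centres and applies sqrt-SD Pareto divisors", {
  x <- cbind(a = c(1, 1, 1), b = c(0, 4, 8))
  sc <- suppressWarnings(scale_columns(x, "pareto"))
  expect_equal(unname(sc$scaled[, "a"]), c(0, 0, 0))
  expect_equal(unname(sc$spec$column_divisors), c(1, 2))  # sd(b) = 4
  expect_true(sc$spec$zero_variance[["a"]])
  expect_warning(scale_columns(x, "pareto"), "zero-variance")

  mc <- scale_columns(x, "mean_center")
  expect_equal(unname(colMeans(mc$scaled)), c(0, 0))

  # refit on scaled data: second-pass divisors equal sqrt of the new SDs
  set.seed(3)
  y <- matrix(rnorm(60, sd = rep(c(1, 5, 20), each = 20)), ncol = 3)
  first <- scale_columns(y, "pareto")
  second <- scale_columns(first$scaled, "pareto")
  expect_equal(unname(second$spec$column_divisors),
               unname(sqrt(apply(first$scaled, 2, sd))), tolerance = 1e-9)

  expect_error(scale_columns(matrix(1:3, nrow = 1)), "insufficient")
})

test_that("PCA matches the SVD decomposition oracle up to component sign", {
  set.seed(11)
  # rank-1 matrix: one component carries all the variance
  r1 <- outer(rnorm(6), rnorm(10))
  p1 <- fit_pca(r1, 1)
  expect_equal(p1$explained_variance_fraction, 1, tolerance = 1e-9)

  x <- matrix(rnorm(300), nrow = 6)
  k <- 4
  fit <- fit_pca(x, k)
  oracle <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in 1:k) {
    s <- sign(sum(fit$loadings[, j] * oracle$rotation[, j]))
    expect_equal(fit$loadings[, j], s * unname(oracle$rotation[, j]),
                 tolerance = 1e-8)
    expect_equal(fit$scores[, j], s * unname(oracle$x[, j]), tolerance = 1e-8)
  }
  expect_equal(fit$explained_variance_fraction,
               unname(oracle$sdev[1:k]^2 / sum(oracle$sdev^2)),
               tolerance = 1e-9)
  # orthonormal loadings, non-increasing explained fractions
  expect_equal(crossprod(fit$loadings), diag(k), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$explained_variance_fraction) <= 1e-12))

  # recomputation oracle on the matrix with a duplicated sample row
  xd <- rbind(x, x[1, ])
  fit2 <- fit_pca(xd, k)
  oracle2 <- prcomp(xd)
  for (j in 1:k) {
    s <- sign(sum(fit2$loadings[, j] * oracle2$rotation[, j]))
    expect_equal(fit2$loadings[, j], s * unname(oracle2$rotation[, j]),
                 tolerance = 1e-6)
  }

  expect_error(fit_pca(x, 7), "between 1 and")
})

test_that("OPLS-DA with no orthogonal component reduces to one-component PLS", {
  skip_if_not_installed("mixOmics")
  set.seed(21)
  x <- matrix(rnorm(13 * 40), nrow = 13)
  labels <- c(rep("control", 6), rep("case", 7))
  x[labels == "case", 1:3] <- x[labels == "case", 1:3] + 1.5

  fit <- fit_oplsda(x, labels, n_orth = 0, scaling = "mean_center")
  y <- ifelse(labels == "case", 1, -1)
  oracle <- mixOmics::pls(x, y, ncomp = 1, scale = FALSE, mode = "regression")
  t_oracle <- unname(oracle$variates$X[, 1])
  s <- sign(sum(fit$t_pred * t_oracle))
  expect_lt(max(abs(fit$t_pred - s * t_oracle)), 1e-8)
})

test_that("a single informative column earns correlation loading +/-1", {
  labels <- c(rep("control", 6), rep("case", 7))
  x <- matrix(5, nrow = 13, ncol = 8)          # constant background
  x[, 4] <- ifelse(labels == "case", 2, 1)     # the only informative bin
  fit <- suppressWarnings(fit_oplsda(x, labels, n_orth = 0))
  expect_equal(abs(fit$corr_loadings[4]), 1, tolerance = 1e-9)
  expect_equal(fit$corr_loadings[-4], rep(0, 7))
  # sign convention: elevated in the case group means positive r
  expect_gt(fit$corr_loadings[4], 0)
  expect_gt(mean(fit$t_pred[labels == "case"]), 0)
})

test_that("OPLS model is equivariant under sample permutation and has valid metrics", {
  set.seed(31)
  x <- matrix(rnorm(13 * 30), nrow = 13)
  labels <- c(rep("control", 6), rep("case", 7))
  x[labels == "case", 1:4] <- x[labels == "case", 1:4] + 2
  fit <- fit_oplsda(x, labels, n_orth = 1)

  perm <- sample(13)
  fitp <- fit_oplsda(x[perm, ], labels[perm], n_orth = 1)
  expect_equal(fitp$t_pred, fit$t_pred[perm], tolerance = 1e-9)
  expect_equal(fitp$corr_loadings, fit$corr_loadings, tolerance = 1e-9)

  expect_gte(fit$r2x, 0); expect_lte(fit$r2x, 1)
  expect_true(all(abs(fit$corr_loadings) <= 1 + 1e-9))
  # unit-norm predictive weights; orthogonal weights orthogonal to them
  expect_equal(sum(fit$w_pred^2), 1, tolerance = 1e-9)
  expect_equal(sum(fit$w_pred * fit$w_orth[[1]]), 0, tolerance = 1e-8)

  expect_error(fit_oplsda(x, rep(c("a", "b", "c"), length.out = 13)),
               "two classes")
  expect_error(fit_oplsda(x, rep("a", 13)), "two classes")
})

test_that("orthogonal components absorb class-unrelated structure", {
  set.seed(41)
  labels <- c(rep("control", 6), rep("case", 7))
  y <- ifelse(labels == "case", 1, -1)
  base <- matrix(rnorm(13 * 20), nrow = 13)
  base[, 1] <- y + rnorm(13, sd = 0.2)

  # a strong structured pattern essentially unrelated to class, absent from
  # the baseline matrix so the two fits are comparable
  set.seed(4)
  v <- rnorm(13); v <- v - mean(v)
  yc <- y - mean(y)
  v <- v - sum(v * yc) / sum(yc^2) * yc + 0.03 * rnorm(13)
  base <- base - v %*% crossprod(v, base) / sum(v^2)
  extra <- cbind(base, 30 * v, 25 * v, 20 * v)

  angle <- function(a, b) {
    acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
  }
  t0 <- fit_oplsda(base, labels, n_orth = 0, scaling = "mean_center")$t_pred
  with1 <- fit_oplsda(extra, labels, n_orth = 1, scaling = "mean_center")$t_pred
  with0 <- fit_oplsda(extra, labels, n_orth = 0, scaling = "mean_center")$t_pred
  expect_lt(angle(t0, with1), 5)
  expect_gt(angle(t0, with0), angle(t0, with1))
})

test_that("cross-validated Q2 rewards real class structure and flags degenerate folds", {
  set.seed(51)
  labels <- c(rep("control", 6), rep("case", 7))
  x <- matrix(rnorm(13 * 25, sd = 0.01), nrow = 13)
  x[, 7] <- ifelse(labels == "case", 2, 1)   # near-perfect predictor column
  q2 <- cross_validated_q2(x, labels, n_orth = 1, folds = 7)
  expect_gt(q2, 0.9)
  expect_lte(q2, 1)

  # alternating labels + 2 venetian-blind folds give single-class training
  expect_error(
    cross_validated_q2(matrix(rnorm(16), 4), c("a", "b", "a", "b"), folds = 2),
    "degenerate fold")
  expect_error(cross_validated_q2(x, labels, folds = 1), "folds")
})
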