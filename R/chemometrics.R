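#' Column scaling for multivariate modelling
#'
#' `mean_center` subtracts column means; `pareto` additionally divides each
#' column by the square root of its standard deviation, damping the dominance
#' of intense peaks while keeping some weighting by magnitude. Zero-variance
#' columns are centred and passed through with divisor 1 (with a warning),
#' so empty bins never cause division by zero.
#'
#' @param x Numeric matrix (samples x variables), at least 2 rows.
#' @param kind `"mean_center"` or `"pareto"`.
#' @param quiet Suppress the zero-variance warning (used inside
#'   cross-validation loops).
#' @return List with `scaled` (matrix) and `spec` (class `scaling_spec`:
#'   `kind`, `column_means`, `column_divisors`, `zero_variance` flags).
#' @export
scale_columns <- function(x, kind = c("mean_center", "pareto"), quiet = FALSE) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("insufficient data: scaling needs at least 2 rows")
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0
  div <- rep(1, ncol(x))
  if (kind == "pareto") {
    div[!zero] <- sqrt(sds[!zero])
    if (any(zero) && !quiet) {
      warning(sum(zero), " zero-variance column(s) passed through with divisor 1")
    }
  }
  scaled <- sweep(sweep(x, 2, mu, "-"), 2, div, "/")
  spec <- structure(list(kind = kind, column_means = mu,
                         column_divisors = div, zero_variance = zero),
                    class = "scaling_spec")
  list(scaled = scaled, spec = spec)
}

apply_scaling <- function(x, spec) {
  sweep(sweep(as.matrix(x), 2, spec$column_means, "-"),
        2, spec$column_divisors, "/")
}

#' Principal component analysis by singular value decomposition
#'
#' Mean-centres the matrix and computes successive orthogonal components of
#' maximal variance. Used for unsupervised quality verification of binned
#' spectra before any supervised modelling.
#'
#' @param x Numeric matrix (samples x variables).
#' @param k Number of components, at most `min(nrow(x) - 1, ncol(x))`.
#' @return Object of class `pca_model`: `scores` (samples x k), `loadings`
#'   (variables x k, orthonormal columns), `explained_variance_fraction`
#'   (fraction of total variance per component, non-increasing).
#' @export
fit_pca <- function(x, k = 2) {
  x <- as.matrix(x)
  kmax <- min(nrow(x) - 1, ncol(x))
  if (k < 1 || k > kmax) {
    stop("`k` must be between 1 and min(samples - 1, variables) = ", kmax)
  }
  xc <- sweep(x, 2, colMeans(x), "-")
  sv <- svd(xc)
  total_var <- sum(sv$d^2)
  structure(list(scores = sv$u[, 1:k, drop = FALSE] %*%
                   diag(sv$d[1:k], nrow = k),
                 loadings = sv$v[, 1:k, drop = FALSE],
                 explained_variance_fraction = sv$d[1:k]^2 / total_var),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; explained variance: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

encode_labels <- function(labels) {
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) {
    stop("unsupported design: exactly two classes required, got ", length(lev))
  }
  # "case"/"control" orders so that case = +1; otherwise the second sorted
  # level is the positive (case) class.
  pos <- if (all(c("case", "control") %in% lev)) "case" else lev[2]
  y <- ifelse(as.character(labels) == pos, 1, -1)
  if (min(table(labels)) < 2) stop("each class needs at least 2 samples")
  list(y = y, positive = pos)
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis: class
#' membership is encoded as centred +/-1, the predictive weight direction is
#' `w = X'y / (y'y)` (normalized), and `n_orth` orthogonal components — each
#' capturing structured variation uncorrelated with class — are removed from
#' X before the single predictive component is extracted. Per-variable
#' correlation loadings (Pearson r between the predictive score and each
#' scaled, undeflated variable) and covariance loadings give the
#' back-scaled interpretation used to rank metabolite bins.
#'
#' The predictive score is oriented so that the case-group mean score is
#' positive, making positive correlation loadings mean "elevated in the case
#' (stressed) group".
#'
#' @param x Numeric matrix or `binned_matrix` (samples x bins).
#' @param labels Two-level class vector; with levels `control`/`case`, `case`
#'   is the positive class.
#' @param n_orth Number of orthogonal components (0 gives plain PLS1).
#' @param scaling `"pareto"` (default) or `"mean_center"`.
#' @param quiet Suppress scaling warnings.
#' @return Object of class `opls_model` with predictive score/loading/weight
#'   vectors, per-orthogonal-component vectors, `n_orth`, `r2x`,
#'   `corr_loadings`, `cov_loadings`, the scaling spec and class encoding.
#'   `q2` is `NA` until filled by [cross_validated_q2()].
#' @export
fit_oplsda <- function(x, labels, n_orth = 1,
                       scaling = c("pareto", "mean_center"), quiet = FALSE) {
  if (inherits(x, "binned_matrix")) {
    if (missing(labels)) labels <- x$groups
    x <- x$values
  }
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), n_orth >= 0)
  enc <- encode_labels(labels)
  y <- enc$y - mean(enc$y)
  if (all(y == 0)) stop("invalid labels: constant class vector")

  sc <- scale_columns(x, scaling, quiet = quiet)
  x0 <- sc$scaled          # scaled, undeflated: correlation-loading reference
  xd <- x0                 # working copy, deflated in place
  ss_total <- sum(x0^2)

  w <- drop(crossprod(xd, y)) / sum(y^2)
  w <- w / sqrt(sum(w^2))

  w_orth <- p_orth <- t_orth <- list()
  for (comp in seq_len(n_orth)) {
    t_ <- drop(xd %*% w)
    p_ <- drop(crossprod(xd, t_)) / sum(t_^2)
    wo <- p_ - sum(w * p_) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break   # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(xd %*% wo)
    po <- drop(crossprod(xd, to)) / sum(to^2)
    xd <- xd - tcrossprod(to, po)
    w_orth[[comp]] <- wo; t_orth[[comp]] <- to; p_orth[[comp]] <- po
  }

  t_pred <- drop(xd %*% w)
  p_pred <- drop(crossprod(xd, t_pred)) / sum(t_pred^2)

  # orient so the case-group mean predictive score is positive
  if (mean(t_pred[enc$y == 1]) < 0) {
    w <- -w; t_pred <- -t_pred; p_pred <- -p_pred
  }

  ss_model <- sum(t_pred^2) * sum(p_pred^2) +
    sum(vapply(seq_along(t_orth),
               function(i) sum(t_orth[[i]]^2) * sum(p_orth[[i]]^2), numeric(1)))
  r2x <- ss_model / ss_total

  col_sd <- apply(x0, 2, stats::sd)
  ok <- col_sd > 0
  corr <- numeric(ncol(x0))
  corr[ok] <- drop(stats::cor(t_pred, x0[, ok, drop = FALSE]))
  covl <- drop(crossprod(x0, t_pred - mean(t_pred))) / (nrow(x0) - 1)

  structure(list(t_pred = t_pred, p_pred = p_pred, w_pred = w,
                 t_orth = t_orth, p_orth = p_orth, w_orth = w_orth,
                 n_orth = length(t_orth), r2x = r2x, q2 = NA_real_,
                 corr_loadings = corr, cov_loadings = covl,
                 scaling = sc$spec, labels = labels,
                 positive_class = enc$positive),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> 1 predictive + %d orthogonal component(s); R2X = %.3f%s\n",
              x$n_orth, x$r2x,
              if (is.na(x$q2)) "" else sprintf(", Q2 = %.3f", x$q2)))
  invisible(x)
}

# Predict OPLS predictive scores for new rows given a fitted model:
# scale with the training spec, strip the orthogonal components, project.
predict_opls_scores <- function(model, newx) {
  xs <- apply_scaling(newx, model$scaling)
  for (i in seq_along(model$w_orth)) {
    to <- drop(xs %*% model$w_orth[[i]])
    xs <- xs - tcrossprod(to, model$p_orth[[i]])
  }
  drop(xs %*% model$w_pred)
}

#' Cross-validated predictive ability Q2
#'
#' Q2 = 1 - PRESS / SS, where PRESS accumulates squared errors of held-out
#' class predictions and SS is the total sum of squares of the centred class
#' vector. Folds follow a deterministic venetian-blind scheme (sample i goes
#' to fold ((i - 1) mod folds) + 1), and scaling is refit on every training
#' split so no information leaks from held-out samples. Held-out predictions
#' are the fitted linear regression of y on the predictive score, evaluated
#' at the held-out score.
#'
#' @param x Numeric matrix or `binned_matrix`.
#' @param labels Two-level class vector.
#' @param n_orth Orthogonal components per fold model.
#' @param folds Number of venetian-blind folds (default 7).
#' @param scaling Scaling refit within each fold.
#' @return Q2 (a number \eqn{\le} 1; negative means worse than predicting
#'   the mean).
#' @export
cross_validated_q2 <- function(x, labels, n_orth = 1, folds = 7,
                               scaling = c("pareto", "mean_center")) {
  if (inherits(x, "binned_matrix")) {
    if (missing(labels)) labels <- x$groups
    x <- x$values
  }
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (folds < 2 || folds > n) stop("`folds` must be between 2 and n samples")
  enc <- encode_labels(labels)
  y <- enc$y
  fold_id <- ((seq_len(n) - 1) %% folds) + 1

  press <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    if (length(unique(labels[!test])) < 2) {
      stop("degenerate fold ", f, ": training split contains a single class")
    }
    fit <- fit_oplsda(x[!test, , drop = FALSE], labels[!test],
                      n_orth = n_orth, scaling = scaling, quiet = TRUE)
    y_train <- y[!test]
    b <- sum(fit$t_pred * (y_train - mean(y_train))) / sum(fit$t_pred^2)
    t_new <- predict_opls_scores(fit, x[test, , drop = FALSE])
    # fold models orient by their own training labels; orientation matches
    # the global encoding because both use the same positive class
    y_hat <- mean(y_train) + b * t_new
    press <- press + sum((y[test] - y_hat)^2)
  }
  1 - press / sum((y - mean(y))^2)
}
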