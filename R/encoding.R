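#' Fit a voxelwise encoding model
#'
#' Linearizing encoding model: stimulus features -> per-vertex response
#' amplitudes. Two variants are provided. `"pca_ols"` reduces the training
#' features to at most `n_components` principal components (fitted on the
#' training images only, mean-centered, unscaled) and fits ordinary least
#' squares per vertex. `"ridge"` skips the PCA and fits per-vertex ridge
#' regression with the penalty chosen per vertex by k-fold cross-validation
#' over a log-spaced grid.
#'
#' @param train_features Numeric matrix, images x features.
#' @param train_responses Numeric matrix, images x vertices (trial-averaged
#'   responses aligned to the feature rows).
#' @param kind `"pca_ols"` or `"ridge"`.
#' @param n_components PCA rank cap for `"pca_ols"` (capped at
#'   images - 1 and at the feature count, with a warning when fewer than
#'   requested are available).
#' @param lambda_grid Ridge penalty grid.
#' @param n_folds Cross-validation folds for ridge.
#' @param seed Seed for the fold assignment.
#' @return An `encoding_model` with the projection (if any), per-vertex
#'   weights and intercepts, and the fitted configuration.
#' @export
fit_encoding <- function(train_features, train_responses,
                         kind = c("pca_ols", "ridge"), n_components = 250L,
                         lambda_grid = 10^seq(-2, 5, length.out = 8),
                         n_folds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(train_features); Y <- as.matrix(train_responses)
  if (nrow(X) != nrow(Y)) stop("features and responses are misaligned")
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("non-finite inputs")
  n <- nrow(X)
  if (kind == "pca_ols") {
    q <- min(n_components, n - 1L, ncol(X))
    if (q < n_components)
      warning(sprintf("only %d components available (requested %d)", q, n_components))
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc, nu = 0, nv = q)
    keep <- sv$d[seq_len(q)] > max(sv$d) * 1e-10
    V <- sv$v[, keep, drop = FALSE]
    Z <- Xc %*% V
    fit <- stats::lm.fit(cbind(1, Z), Y)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    model <- list(kind = kind, feature_means = mu, pca_basis = V,
                  intercept = coefs[1, ], weights = coefs[-1, , drop = FALSE])
  } else {
    mu <- colMeans(X); my <- colMeans(Y)
    Xc <- sweep(X, 2, mu); Yc <- sweep(Y, 2, my)
    folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
    cv_err <- matrix(0, length(lambda_grid), ncol(Y))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      sv <- svd(Xc[tr, , drop = FALSE])
      pos <- sv$d > max(sv$d) * 1e-12
      U <- sv$u[, pos, drop = FALSE]; d <- sv$d[pos]; V <- sv$v[, pos, drop = FALSE]
      UtY <- crossprod(U, Yc[tr, , drop = FALSE])
      XteV <- Xc[!tr, , drop = FALSE] %*% V
      for (li in seq_along(lambda_grid)) {
        shrink <- d / (d^2 + lambda_grid[li])
        pred <- XteV %*% (shrink * UtY)
        cv_err[li, ] <- cv_err[li, ] + colSums((Yc[!tr, , drop = FALSE] - pred)^2)
      }
    }
    best <- apply(cv_err, 2, which.min)
    sv <- svd(Xc)
    pos <- sv$d > max(sv$d) * 1e-12
    U <- sv$u[, pos, drop = FALSE]; d <- sv$d[pos]; V <- sv$v[, pos, drop = FALSE]
    UtY <- crossprod(U, Yc)
    W <- matrix(0, ncol(X), ncol(Y))
    for (li in sort(unique(best))) {
      cols <- best == li
      shrink <- d / (d^2 + lambda_grid[li])
      W[, cols] <- V %*% (shrink * UtY[, cols, drop = FALSE])
    }
    # features are centered at prediction time, so the intercept is the
    # training response mean
    model <- list(kind = kind, feature_means = mu, pca_basis = NULL,
                  intercept = my, weights = W, lambda = lambda_grid[best])
  }
  structure(model, class = "encoding_model")
}

#' Predict responses from an encoding model
#' @param object An `encoding_model`.
#' @param features Images x features matrix.
#' @param ... Unused.
#' @return Images x vertices matrix of predicted responses.
#' @export
predict.encoding_model <- function(object, features, ...) {
  Xc <- sweep(as.matrix(features), 2, object$feature_means)
  Z <- if (is.null(object$pca_basis)) Xc else Xc %*% object$pca_basis
  sweep(Z %*% object$weights, 2, object$intercept, "+")
}

# per-column Pearson correlation of two matrices; zero-variance columns
# give 0 (no linear relation measurable)
colwise_cor <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  den <- sqrt(colSums(A^2) * colSums(B^2))
  r <- ifelse(den > 0, colSums(A * B) / den, 0)
  pmin(1, pmax(-1, r))
}

#' Evaluate generalization of an encoding model
#'
#' Correlates predicted with recorded (trial-averaged) responses per
#' vertex across the test images; negative correlations are set to zero
#' before squaring; the resulting explained variance is divided by the
#' test split's own noise ceiling (as a fraction of 1). Normalized scores
#' may exceed 1 by noise and are reported unclipped unless `clip` is set.
#'
#' @param model An `encoding_model`.
#' @param test_features Test images x features.
#' @param test_responses Test images x vertices, trial-averaged.
#' @param nc Per-vertex noise ceiling in percent (0-100) for the test
#'   split; `NULL` skips normalization.
#' @param nc_threshold Vertices with noise-ceiling fraction at or below
#'   this value are flagged out of map averages (mask returned, scores
#'   kept).
#' @param clip Clip normalized scores to [0, 1].
#' @return A `generalization_score`: list with `r`, `r2`,
#'   `nc_normalized`, `mask`.
#' @export
evaluate_encoding <- function(model, test_features, test_responses, nc = NULL,
                              nc_threshold = 0.3, clip = FALSE) {
  if (nrow(test_features) < 3L) stop("need at least 3 test images")
  pred <- predict(model, test_features)
  r <- colwise_cor(pred, as.matrix(test_responses))
  r2 <- pmax(r, 0)^2
  nc_normalized <- mask <- NULL
  if (!is.null(nc)) {
    frac <- nc / 100
    nc_normalized <- ifelse(frac > 0, r2 / frac, NA_real_)
    if (clip) nc_normalized <- pmin(1, pmax(0, nc_normalized))
    mask <- select_vertices(frac, nc_threshold)
  }
  structure(list(r = r, r2 = r2, nc_normalized = nc_normalized, mask = mask),
            class = "generalization_score")
}

#' Compare two models' normalized scores across participants
#'
#' Computes the per-vertex difference in noise-ceiling-normalized
#' explained variance, averaged over the participants whose vertex passes
#' the noise-ceiling rule under both models, and a one-sided paired t-test
#' over participant mean scores (A greater than B).
#'
#' @param score_a,score_b Participants x vertices matrices of normalized
#'   scores.
#' @param mask_a,mask_b Optional participants x vertices logical masks
#'   (vertex usable for that participant under each model's test split).
#' @return A list with `delta` (per-vertex mean difference), `t`, `p`,
#'   `participant_means` (two-column matrix). With fewer than 2
#'   participants, or zero variance of the paired differences, `t` and
#'   `p` are `NA`.
#' @export
compare_models <- function(score_a, score_b, mask_a = NULL, mask_b = NULL) {
  score_a <- as.matrix(score_a); score_b <- as.matrix(score_b)
  stopifnot(all(dim(score_a) == dim(score_b)))
  ok <- !is.na(score_a) & !is.na(score_b)
  if (!is.null(mask_a)) ok <- ok & mask_a
  if (!is.null(mask_b)) ok <- ok & mask_b
  d <- score_a - score_b
  d[!ok] <- NA
  delta <- colMeans(d, na.rm = TRUE)
  pm <- cbind(a = rowMeans(ifelse(ok, score_a, NA), na.rm = TRUE),
              b = rowMeans(ifelse(ok, score_b, NA), na.rm = TRUE))
  n <- nrow(score_a)
  if (n < 2L || stats::sd(pm[, 1] - pm[, 2]) == 0) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    ht <- stats::t.test(pm[, 1], pm[, 2], paired = TRUE, alternative = "greater")
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  list(delta = delta, t = tt$statistic, p = tt$p.value,
       participant_means = pm)
}
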