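# linear ground-truth world: responses = features %*% W (+ noise)
linear_world <- function(n_img, p, n_vert, noise_sd = 0, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n_img * p), n_img, p)
    W <- matrix(stats::rnorm(p * n_vert), p, n_vert)
    Y <- X %*% W + matrix(stats::rnorm(n_img * n_vert, sd = noise_sd),
                          n_img, n_vert)
    list(X = X, W = W, Y = Y)
  })
}

test_that("noise-free linear responses are recovered exactly on held-out images", {
  w <- linear_world(120, 10, 5, noise_sd = 0, seed = 2L)
  tr <- 1:80; te <- 81:120
  m <- fit_encoding(w$X[tr, ], w$Y[tr, ], kind = "pca_ols", n_components = 10) |>
    suppressWarnings()
  sc <- evaluate_encoding(m, w$X[te, ], w$Y[te, ])
  expect_true(all(abs(sc$r - 1) < 1e-6))
  expect_true(all(abs(sc$r2 - 1) < 1e-6))
})

test_that("PCA keeps the requested rank and matches the eigendecomposition oracle", {
  w <- linear_world(300, 40, 2, seed = 3L)
  m <- fit_encoding(w$X, w$Y, n_components = 12)
  expect_equal(ncol(m$pca_basis), 12)
  # oracle: top eigenvectors of the covariance span the same subspace and
  # capture at least as much variance as any other rank-12 projection
  Xc <- sweep(w$X, 2, colMeans(w$X))
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$vectors[, 1:12]
  proj_var <- function(V) sum((Xc %*% V)^2)
  expect_equal(proj_var(m$pca_basis), proj_var(ev), tolerance = 1e-8)
  rand_V <- qr.Q(qr(matrix(stats::rnorm(40 * 12), 40, 12)))
  expect_gte(proj_var(m$pca_basis) + 1e-8, proj_var(rand_V))
  expect_warning(fit_encoding(w$X[1:5, ], w$Y[1:5, ], n_components = 250),
                 "components available")
})

test_that("ridge at tiny lambda matches OLS on a full-rank design", {
  w <- linear_world(200, 15, 4, noise_sd = 0.5, seed = 4L)
  m_ridge <- fit_encoding(w$X, w$Y, kind = "ridge",
                          lambda_grid = 1e-8, n_folds = 3)
  m_ols <- suppressWarnings(
    fit_encoding(w$X, w$Y, kind = "pca_ols", n_components = 15))
  # compare effective coefficients in feature space
  B_ols <- m_ols$pca_basis %*% m_ols$weights
  expect_lt(max(abs(m_ridge$weights - B_ols)) / max(abs(B_ols)), 1e-6)
})

test_that("held-out prediction is strong at NCSNR 1 on a 1000-image training set", {
  feats <- withr::with_seed(5L, matrix(stats::rnorm(1100 * 60), 1100, 60))
  sim <- simulate_responses(feats, n_vertices = 40L, ncsnr = 1, repeats = 1L,
                            seed = 6L)
  tr <- 1:1000; te <- 1001:1100
  train_Y <- sim$responses$betas[tr, ]
  m <- suppressWarnings(fit_encoding(feats[tr, ], train_Y, n_components = 250))
  # held-out evaluation against 3-repeat trial-averaged responses
  te_sim <- simulate_responses(feats, n_vertices = 40L, ncsnr = 1, repeats = 3L,
                               seed = 6L)
  te_avg <- average_by_image(te_sim$responses, images = te)
  sc <- evaluate_encoding(m, feats[te, ], te_avg)
  expect_gte(stats::median(sc$r), 0.8)
})

test_that("normalized score is ~1 for a perfect model at any noise level", {
  feats <- withr::with_seed(7L, matrix(stats::rnorm(284 * 20), 284, 20))
  for (s in c(0.5, 2)) {
    scores <- vapply(1:50, function(rep) {
      sim <- simulate_responses(feats, n_vertices = 30L, ncsnr = s,
                                repeats = 3L, seed = 100L + rep)
      avg <- average_by_image(sim$responses)
      s_hat <- compute_ncsnr(sim$responses, zscore = FALSE)
      nc <- ncsnr_to_noise_ceiling(s_hat, 3)
      # perfect model: predictions are the true noiseless signal
      r <- visood:::colwise_cor(sim$truth$signal, avg)
      ratio <- pmax(r, 0)^2 / (nc / 100)
      mean(ratio[is.finite(ratio)])   # a zero NC estimate yields no ratio
    }, numeric(1))
    expect_lt(abs(mean(scores) - 1), 0.1)
  }
})

test_that("prediction correlation ignores gain and offset of the predictions", {
  w <- linear_world(60, 8, 3, noise_sd = 0.2, seed = 8L)
  m <- suppressWarnings(fit_encoding(w$X[1:40, ], w$Y[1:40, ], n_components = 8))
  sc <- evaluate_encoding(m, w$X[41:60, ], w$Y[41:60, ])
  rescaled <- evaluate_encoding(m, w$X[41:60, ], 3.7 * w$Y[41:60, ] + 5)
  expect_equal(sc$r, rescaled$r, tolerance = 1e-10)
})

test_that("model comparison detects a planted participant-level difference", {
  # power oracle: true mean difference 0.1, SD 0.05, N = 8 participants
  hits <- vapply(1:200, function(rep) {
    withr::with_seed(1000L + rep, {
      base <- matrix(stats::runif(8 * 20, 0.3, 0.7), 8, 20)
      delta <- stats::rnorm(8, 0.1, 0.05)
      cm <- compare_models(base + delta, base)
      cm$p < 0.05
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("model comparison is antisymmetric and degenerate-safe", {
  a <- matrix(stats::runif(16), 4, 4)
  b <- matrix(stats::runif(16), 4, 4)
  ab <- compare_models(a, b)
  ba <- compare_models(b, a)
  expect_equal(ab$delta, -ba$delta)
  same <- compare_models(a, a)
  expect_true(all(same$delta == 0))
  expect_true(is.na(same$t) && is.na(same$p))
})
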