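test_that("the simulator hits its target signal-to-noise ratio by construction", {
  feats <- withr::with_seed(1L, matrix(stats::rnorm(284 * 30), 284, 30))
  sim <- simulate_responses(feats, n_vertices = 100L, ncsnr = 1, repeats = 3L,
                            seed = 2L)
  # empirical signal SD / noise SD per vertex, averaged over 100 vertices
  ratio <- vapply(1:100, function(v) {
    sig_sd <- stats::sd(sim$truth$signal[, v])
    resid <- sim$responses$betas[, v] -
      sim$truth$signal[sim$responses$trial_image, v]
    sig_sd / stats::sd(resid)
  }, numeric(1))
  expect_gt(mean(ratio), 0.95)
  expect_lt(mean(ratio), 1.05)
})

test_that("noise-free simulation gives perfect model evaluation", {
  feats <- withr::with_seed(3L, matrix(stats::rnorm(60 * 10), 60, 10))
  sim <- simulate_responses(feats, n_vertices = 8L, ncsnr = 1, repeats = 1L,
                            noise_sd = 0, seed = 4L)
  m <- suppressWarnings(
    fit_encoding(feats[1:40, ], sim$responses$betas[1:40, ], n_components = 10))
  sc <- evaluate_encoding(m, feats[41:60, ], sim$responses$betas[41:60, ])
  expect_true(all(sc$r > 1 - 1e-6))
  expect_error(simulate_responses(feats, ncsnr = 0, noise_sd = 0), "constant")
})

test_that("a feature rotation of pi/2 degrades OOD generalization", {
  feats <- withr::with_seed(5L, matrix(stats::rnorm(120 * 20), 120, 20))
  cls <- rep(c("id", "ood"), each = 60)
  wins <- vapply(1:100, function(rep) {
    sim <- simulate_responses(feats, n_vertices = 20L, ncsnr = 1.5,
                              repeats = 2L, class_of = cls,
                              ood_rotation = c(ood = pi / 2),
                              seed = 700L + rep)
    avg <- average_by_image(sim$responses)
    m <- suppressWarnings(
      fit_encoding(feats[1:50, ], avg[1:50, ], n_components = 20))
    id_sc <- evaluate_encoding(m, feats[51:60, ], avg[51:60, ])
    ood_sc <- evaluate_encoding(m, feats[61:120, ], avg[61:120, ])
    stats::median(id_sc$r2) > stats::median(ood_sc$r2)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("distributional distance rises monotonically with the planted perturbation", {
  feats <- withr::with_seed(6L, matrix(stats::rnorm(150 * 15), 150, 15))
  shifts <- c(0, 0.5, 1, 1.5, 2)
  cls <- c(rep("train", 100), rep("probe", 50))
  rho <- vapply(1:20, function(rep) {
    d_at <- vapply(seq_along(shifts), function(si) {
      sim <- simulate_responses(feats, n_vertices = 30L, ncsnr = 2,
                                repeats = 1L, class_of = cls,
                                ood_shift = c(probe = shifts[si]),
                                seed = 900L + rep)   # same seed across shifts
      emb <- mds_embed(sim$responses$betas, dims = 2)
      distributional_distance(emb, test_idx = 101:150, ref_idx = 1:100,
                              class_of = rep("probe", 50))[["probe"]]
    }, numeric(1))
    stats::cor(shifts, d_at, method = "spearman")
  }, numeric(1))
  expect_gte(stats::median(rho), 0.9)
})

test_that("naturalistic fixtures are reproducible scene-like images", {
  a <- make_naturalistic_fixtures(3, seed = 7L, side = 256L)
  b <- make_naturalistic_fixtures(3, seed = 7L, side = 256L)
  expect_identical(a, b)
  expect_false(identical(a[[1]], make_naturalistic_fixtures(1, seed = 8L,
                                                            side = 256L)[[1]]))
  expect_true(all(vapply(a, function(m) all(m >= 0 & m <= 1), logical(1))))
  slopes <- vapply(a, spectral_slope, numeric(1))
  expect_true(all(slopes > -1.4 & slopes < -0.6))
})

test_that("fixture scenes and spiral gratings are separable in feature space", {
  ex <- oriented_energy_extractor(wavelengths = c(4, 8, 16, 32), n_orient = 6L,
                                  grid = 4L)
  scenes <- make_naturalistic_fixtures(12, seed = 9L, side = 256L)
  g <- display_geometry(320, 168, 16, 8.4)
  spirals <- lapply(1:12, function(i)
    make_spiral_grating(g, c(6, 20, 37)[(i %% 3) + 1], "A", phase = i))
  scenes_pre <- lapply(scenes, preprocess_image, sqrt_transform = FALSE)
  X <- rbind(extract_features(scenes_pre, ex), extract_features(spirals, ex))
  y <- rep(c(0, 1), each = 12)
  tr <- c(1:8, 13:20); te <- setdiff(1:24, tr)
  # nearest-centroid margin classifier on standardized features
  mu <- colMeans(X[tr, ]); sd <- apply(X[tr, ], 2, stats::sd); sd[sd == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  c0 <- colMeans(Z[tr[y[tr] == 0], ]); c1 <- colMeans(Z[tr[y[tr] == 1], ])
  pred <- as.numeric(rowSums(sweep(Z[te, ], 2, c1)^2) <
                       rowSums(sweep(Z[te, ], 2, c0)^2))
  expect_gt(mean(pred == y[te]), 0.9)
})
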