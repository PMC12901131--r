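rigid_transform <- function(points, seed = 1L) {
  withr::with_seed(seed, {
    a <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    if (stats::runif(1) < 0.5) R[, 2] <- -R[, 2]   # reflection
    sweep(points %*% R, 2, stats::rnorm(2, sd = 5), "+")
  })
}

test_that("classical MDS reproduces distances exactly for planar data", {
  pts <- withr::with_seed(1L, matrix(stats::rnorm(40 * 2), 40, 2))
  # embed the plane in a high-dimensional response space by a rigid map
  Q <- withr::with_seed(2L, qr.Q(qr(matrix(stats::rnorm(30 * 2), 30, 2))))
  emb <- mds_embed(pts %*% t(Q), dims = 2)
  d_in <- stats::dist(pts); d_out <- stats::dist(emb$points)
  expect_lt(max(abs(d_out - d_in)) / max(d_in), 1e-8)
  expect_error(mds_embed(matrix(1, 5, 3)), "degenerate")
  expect_error(mds_embed(matrix(stats::rnorm(4), 2, 2)), "3 items")
})

test_that("SMACOF refinement approximates distances on planar data", {
  pts <- withr::with_seed(3L, matrix(stats::rnorm(30 * 2), 30, 2))
  emb <- mds_embed(pts, dims = 2, method = "smacof", seed = 4L, n_iter = 300L)
  d_in <- as.vector(stats::dist(pts)); d_out <- as.vector(stats::dist(emb$points))
  expect_gt(stats::cor(d_in, d_out), 0.99)
})

test_that("distributional distance matches brute-force pair enumeration", {
  # test points at the train centroid; train points symmetric about it
  train <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1))
  test <- rbind(c(0, 0), c(0, 0))
  pts <- rbind(train, test)
  d <- distributional_distance(pts, test_idx = 5:6, ref_idx = 1:4,
                               class_of = c("x", "x"))
  expect_equal(unname(d["x"]), mean(c(2, 2, 1, 1)))   # mean train radius
  # brute force on an arbitrary configuration
  pts2 <- withr::with_seed(5L, matrix(stats::rnorm(20), 10, 2))
  cls <- rep(c("a", "b"),
             length.out = 4)
  d2 <- distributional_distance(pts2, 1:4, 5:10, cls)
  brute <- vapply(c("a", "b"), function(cl) {
    ti <- (1:4)[cls == cl]
    mean(vapply(ti, function(i)
      mean(sqrt(rowSums(sweep(pts2[5:10, ], 2, pts2[i, ])^2))), numeric(1)))
  }, numeric(1))
  expect_equal(d2, brute, tolerance = 1e-12)
  # invariance to rigid transforms (translation, rotation, reflection)
  d3 <- distributional_distance(rigid_transform(pts2, 6L), 1:4, 5:10, cls)
  expect_equal(d2, d3, tolerance = 1e-10)
})

test_that("zero-shot identification ranks the correct image first under perfect prediction", {
  pred <- withr::with_seed(7L, matrix(stats::rnorm(50 * 30), 50, 30))
  res <- zero_shot_identify(pred, pred)
  expect_true(all(res$rank == 1))
  expect_equal(unique(res$candidates), 50)
  expect_error(zero_shot_identify(pred[1, , drop = FALSE], pred[1, , drop = FALSE]),
               ">= 2")
})

test_that("random predictions give chance-level mean rank in the class protocol", {
  withr::with_seed(8L, {
    pred <- matrix(stats::rnorm(64 * 40), 64, 40)
    rec <- matrix(stats::rnorm(64 * 40), 64, 40)
  })
  cls <- rep(letters[1:8], each = 8)
  res <- zero_shot_identify(pred, rec, class_of = cls, n_per_class = 8L,
                            iterations = 200L, seed = 9L)
  chance <- (64 + 1) / 2
  # SE of the grand mean rank across 64 items x 200 iterations
  se <- stats::sd(res$rank) / sqrt(nrow(res))
  expect_lt(abs(mean(res$rank) - chance), 3 * se + 1)
  expect_true(all(res$candidates == 64))
})

test_that("OOD splits isolate a planted distant cluster every time", {
  hits <- vapply(1:100, function(rep) {
    pts <- withr::with_seed(200L + rep, {
      rbind(matrix(stats::rnorm(60 * 2, 0), 60, 2),
            matrix(stats::rnorm(60 * 2, 8), 60, 2),    # well separated
            matrix(stats::rnorm(30 * 2, 40), 30, 2))   # far blob
    })
    sp <- build_ood_splits(pts, k = 3L, n_ood = 20L, n_id = 30L,
                           seed = 300L + rep)
    all(sp$ood_test > 120)
  }, logical(1))
  expect_equal(mean(hits), 1)
})

test_that("OOD splits partition the items with the requested sizes", {
  pts <- withr::with_seed(10L, matrix(stats::rnorm(400 * 2), 400, 2))
  sp <- build_ood_splits(pts, k = 5L, n_ood = 40L, n_id = 60L, seed = 11L)
  expect_length(intersect(sp$train, sp$id_test), 0)
  expect_length(intersect(sp$train, sp$ood_test), 0)
  expect_length(intersect(sp$id_test, sp$ood_test), 0)
  # OOD-cluster items beyond n_ood are excluded from every split
  expect_setequal(c(sp$train, sp$id_test, sp$ood_test, sp$excluded), 1:400)
  expect_true(all(sp$cluster[sp$excluded] == sp$ood_cluster))
  expect_length(sp$id_test, 60)
  expect_true(length(sp$ood_test) <= 40)
  # deterministic given the seed
  sp2 <- build_ood_splits(pts, k = 5L, n_ood = 40L, n_id = 60L, seed = 11L)
  expect_identical(sp, sp2)
  # train <-> OOD distance exceeds train <-> ID distance by construction
  mean_cross <- function(a, b)
    mean(sqrt(outer(rowSums(pts[a, ]^2), rowSums(pts[b, ]^2), "+") -
                2 * pts[a, ] %*% t(pts[b, ])))
  expect_gt(mean_cross(sp$train, sp$ood_test), mean_cross(sp$train, sp$id_test))
  expect_error(build_ood_splits(pts, k = 1L), "k must be")
})

test_that("RSA scores are 1 on self, positive across matched participants, null under permutation", {
  feats <- withr::with_seed(12L, matrix(stats::rnorm(40 * 15), 40, 15))
  # two participants with the same tuning model, independent noise
  reps <- vapply(1:20, function(rep) {
    s1 <- simulate_responses(feats, n_vertices = 60L, ncsnr = 1.5, repeats = 2L,
                             seed = 400L + rep)
    s2 <- simulate_responses(feats, n_vertices = 60L, ncsnr = 1.5, repeats = 2L,
                             seed = 800L + rep)
    rsa <- rsa_compare(list(p1 = average_by_image(s1$responses),
                            p2 = average_by_image(s2$responses)))
    c(self = rsa$scores[1, 1], cross = rsa$scores[1, 2])
  }, numeric(2))
  expect_equal(unname(reps["self", ]), rep(1, 20), tolerance = 1e-12)
  expect_gte(mean(reps["cross", ] > 0), 0.95)
  # permuting one response set's image order nulls the correspondence
  s1 <- simulate_responses(feats, n_vertices = 60L, ncsnr = 1.5, repeats = 2L,
                           seed = 13L)
  avg <- average_by_image(s1$responses)
  perms <- vapply(1:200, function(i) {
    pi <- withr::with_seed(i, sample(nrow(avg)))
    rsa_compare(list(a = avg, b = avg[pi, ]))$scores[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(perms)), 0.05)
})

test_that("distance-performance statistic flags monotone coupling and controls type I error", {
  # perfectly monotone decreasing relation in every participant
  d <- matrix(rep(1:8, times = 4), 4, 8, byrow = TRUE)
  perf <- -d
  st <- distance_performance_stat(d[1, ], perf, alternative = "less")
  expect_true(all(st$rho == -1))
  expect_lt(st$p, 1e-6)
  # true negative coupling, 8 participants: sign of mean rho
  signs <- vapply(1:100, function(rep) {
    withr::with_seed(500L + rep, {
      dist <- stats::runif(8, 1, 5)
      perf <- t(vapply(1:8, function(p) -0.5 * dist + stats::rnorm(8, sd = 0.5),
                       numeric(8)))
      distance_performance_stat(dist, perf, alternative = "less")$mean_rho < 0
    })
  }, logical(1))
  expect_gte(mean(signs), 0.95)
  # independent distance and performance: false-positive rate at alpha 0.05
  fp <- vapply(1:400, function(rep) {
    withr::with_seed(2000L + rep, {
      dist <- stats::runif(8, 1, 5)
      perf <- matrix(stats::rnorm(8 * 8), 8, 8)
      distance_performance_stat(dist, perf, alternative = "less")$p < 0.05
    })
  }, logical(1))
  expect_lte(mean(fp), 0.075)
})

test_that("the univariate averaging chain reduces responses subclass by ROI", {
  feats <- withr::with_seed(14L, matrix(stats::rnorm(12 * 6), 12, 6))
  rms <- lapply(1:2, function(p)
    simulate_responses(feats, n_vertices = 10L, ncsnr = 2, repeats = 2L,
                       seed = 600L + p)$responses)
  roi_of <- rep(c("V1", "V2"), each = 5)
  subclass_of <- rep(c("s1", "s2", "s3"), each = 4)
  prof <- univariate_profile(rms, roi_of, subclass_of)
  expect_equal(dim(prof), c(3L, 2L))
  # oracle: direct nested means for one cell
  oracle <- mean(vapply(1:2, function(p) {
    rm <- rms[[p]]
    avg <- average_by_image(rm)
    mean(rowMeans(avg[1:4, roi_of == "V1"]))
  }, numeric(1)))
  expect_equal(unname(prof["s1", 1]), oracle, tolerance = 1e-12)
})
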