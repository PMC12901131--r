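#' Two-dimensional MDS embedding of response patterns
#'
#' Classical (Torgerson) multidimensional scaling of Euclidean distances
#' between the rows of `responses` (items x vertices). Classical MDS is
#' deterministic; a seeded SMACOF (stress-majorization) refinement is
#' available. All downstream statistics use inter-point distances only,
#' which are invariant to the rotation/reflection ambiguity of the
#' embedding.
#'
#' @param responses Items x vertices matrix (vertices typically appended
#'   across participants upstream).
#' @param dims Embedding dimensionality.
#' @param method `"classical"` or `"smacof"`.
#' @param seed Seed for the SMACOF initialization.
#' @param n_iter SMACOF iterations.
#' @return An `embedding` object: `points` (items x dims), `method`.
#' @export
mds_embed <- function(responses, dims = 2L, method = c("classical", "smacof"),
                      seed = 1L, n_iter = 100L) {
  method <- match.arg(method)
  X <- as.matrix(responses)
  if (nrow(X) < 3L) stop("need at least 3 items")
  D <- stats::dist(X)
  if (max(D) == 0) stop("all items identical; embedding is degenerate")
  if (method == "classical") {
    pts <- stats::cmdscale(D, k = dims)
    if (ncol(pts) < dims)
      pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  } else {
    Dm <- as.matrix(D)
    n <- nrow(Dm)
    pts <- with_seed(seed, matrix(stats::rnorm(n * dims), n, dims))
    for (it in seq_len(n_iter)) {
      E <- as.matrix(stats::dist(pts))
      ratio <- ifelse(E > 0, Dm / E, 0)
      B <- -ratio
      diag(B) <- -rowSums(B)
      pts <- B %*% pts / n
    }
  }
  structure(list(points = pts, method = method), class = "embedding")
}

#' Distributional distance of test classes from a reference set
#'
#' For each class of test items, the mean Euclidean distance in embedding
#' space over all (test item, reference item) pairs. Quantifies the degree
#' to which each class is out-of-distribution relative to the reference
#' (training) responses.
#'
#' @param points Items x dims coordinate matrix (or an `embedding`).
#' @param test_idx,ref_idx Row indices of the test and reference items.
#' @param class_of Class label for each test item (same length as
#'   `test_idx`).
#' @return Named numeric vector of per-class mean distances.
#' @export
distributional_distance <- function(points, test_idx, ref_idx, class_of) {
  if (inherits(points, "embedding")) points <- points$points
  stopifnot(length(test_idx) == length(class_of))
  ref <- points[ref_idx, , drop = FALSE]
  classes <- unique(class_of)
  out <- numeric(0)
  for (cl in classes) {
    ti <- test_idx[class_of == cl]
    if (length(ti) == 0L) { warning("empty class skipped: ", cl); next }
    te <- points[ti, , drop = FALSE]
    # mean over all pairs of ||te_i - ref_j||
    d2 <- outer(rowSums(te^2), rowSums(ref^2), "+") - 2 * te %*% t(ref)
    out[cl] <- mean(sqrt(pmax(d2, 0)))
  }
  out
}

#' Zero-shot identification of stimulus images
#'
#' Correlates each recorded test-response pattern with the
#' model-predicted patterns of a set of candidate images and records the
#' rank of the correct image (1 = highest correlation). Two protocols:
#' with `per_class` sampling, each iteration draws `n_per_class` candidate
#' images per class (always including the target's own class) and ranks
#' within that pool, averaging ranks over iterations; otherwise, all
#' candidates are used once.
#'
#' @param predicted Candidates x vertices matrix of predicted responses.
#' @param recorded Tests x vertices matrix of recorded (trial-averaged)
#'   responses; row `i` corresponds to candidate `target_idx[i]`.
#' @param target_idx Row of `predicted` holding each test item's correct
#'   image (default: same order).
#' @param class_of Candidate class labels (required for the per-class
#'   protocol).
#' @param n_per_class Candidates drawn per class and iteration.
#' @param iterations Number of random candidate draws.
#' @param per_class Use the class-sampling protocol.
#' @param seed Integer seed.
#' @return An `identification_result`: data frame with `rank` (mean rank
#'   per test item) and `candidates` (candidate-set size); chance mean
#'   rank is `(candidates + 1) / 2`.
#' @export
zero_shot_identify <- function(predicted, recorded,
                               target_idx = seq_len(nrow(recorded)),
                               class_of = NULL, n_per_class = 8L,
                               iterations = 1000L, per_class = !is.null(class_of),
                               seed = 1L) {
  predicted <- as.matrix(predicted); recorded <- as.matrix(recorded)
  stopifnot(length(target_idx) == nrow(recorded))
  # correlation of every recorded pattern with every predicted pattern
  R <- stats::cor(t(recorded), t(predicted))
  rank_of <- function(scores, correct_pos) {
    # highest correlation = rank 1; average ranks on ties
    rank(-scores, ties.method = "average")[correct_pos]
  }
  if (!per_class) {
    if (nrow(predicted) < 2L) stop("candidate set must have >= 2 images")
    ranks <- vapply(seq_len(nrow(recorded)), function(i)
      rank_of(R[i, ], target_idx[i]), numeric(1))
    return(structure(data.frame(rank = ranks, candidates = nrow(predicted)),
                     class = c("identification_result", "data.frame")))
  }
  stopifnot(length(class_of) == nrow(predicted))
  classes <- unique(class_of)
  by_class <- split(seq_len(nrow(predicted)), class_of)
  if (any(vapply(by_class, length, integer(1)) < n_per_class))
    stop("every class needs at least n_per_class candidates")
  n_cand <- n_per_class * length(classes)
  acc <- matrix(0, nrow(recorded), iterations)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      draw <- unlist(lapply(by_class, function(ix)
        sample(ix, n_per_class)), use.names = FALSE)
      for (i in seq_len(nrow(recorded))) {
        cand <- draw
        if (!target_idx[i] %in% cand) {
          # replace a random same-class candidate with the target
          same <- which(class_of[cand] == class_of[target_idx[i]])
          cand[same[sample.int(length(same), 1L)]] <- target_idx[i]
        }
        acc[i, it] <- rank_of(R[i, cand], match(target_idx[i], cand))
      }
    }
  })
  structure(data.frame(rank = rowMeans(acc), candidates = n_cand),
            class = c("identification_result", "data.frame"))
}

# k-means++ seeding followed by Lloyd iterations; best of n_start seedings
# by total within-cluster sum of squares
kmeanspp <- function(points, k, seed, n_start = 5L) {
  n <- nrow(points)
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_start)) {
      centers <- matrix(0, k, ncol(points))
      centers[1, ] <- points[sample.int(n, 1L), ]
      d2 <- rowSums(sweep(points, 2, centers[1, ])^2)
      for (j in 2:k) {
        p <- d2 / sum(d2)
        centers[j, ] <- points[sample.int(n, 1L, prob = p), ]
        d2 <- pmin(d2, rowSums(sweep(points, 2, centers[j, ])^2))
      }
      km <- suppressWarnings(stats::kmeans(points, centers = centers,
                                           iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
}

#' Construct train / ID-test / OOD-test splits by embedding clustering
#'
#' Partitions an embedding of candidate responses into `k` clusters
#' (k-means with k-means++ seeding). The OOD cluster is the one whose
#' centroid has the highest mean Euclidean distance to the other `k - 1`
#' centroids; within it, the `n_ood` items with the highest mean distance
#' to the other clusters' centroids form the OOD test split. The ID test
#' split is `n_id` items drawn uniformly from the remaining clusters, and
#' the train split is everything else.
#'
#' @param points Items x dims embedding (or an `embedding`).
#' @param k Number of clusters (>= 2).
#' @param n_ood,n_id Test split sizes. If the OOD cluster holds fewer than
#'   `n_ood` items, all of it is taken with a warning.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train`, `id_test`,
#'   `ood_test`, and `excluded` (OOD-cluster items beyond the `n_ood` most
#'   distant, which belong to no split so that near-OOD responses cannot
#'   leak into training), plus `cluster` assignments and `ood_cluster`.
#' @export
build_ood_splits <- function(points, k = 15L, n_ood = 284L, n_id = 284L,
                             seed = 1L) {
  if (inherits(points, "embedding")) points <- points$points
  if (k < 2L) stop("k must be >= 2")
  if (nrow(points) < 2L * k) stop("need at least 2 items per cluster")
  km <- kmeanspp(points, k, child_seed(seed, 1))
  cen <- km$centers
  cen_d <- as.matrix(stats::dist(cen))
  mean_to_others <- rowSums(cen_d) / (k - 1)
  ood_cluster <- which.max(mean_to_others)
  in_ood <- which(km$cluster == ood_cluster)
  other_cen <- cen[-ood_cluster, , drop = FALSE]
  item_dist <- function(ix) {
    P <- points[ix, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(other_cen^2), "+") - 2 * P %*% t(other_cen)
    rowMeans(sqrt(pmax(d2, 0)))
  }
  if (length(in_ood) < n_ood) {
    warning("OOD cluster smaller than n_ood; taking all of it")
    ood_test <- in_ood
  } else {
    ood_test <- in_ood[order(item_dist(in_ood), decreasing = TRUE)[seq_len(n_ood)]]
  }
  rest <- setdiff(seq_len(nrow(points)), in_ood)
  if (length(rest) < n_id) stop("not enough items outside the OOD cluster")
  id_test <- with_seed(child_seed(seed, 2), sort(sample(rest, n_id)))
  train <- setdiff(rest, id_test)
  # items of the OOD cluster beyond the n_ood most distant belong to no
  # split: they are excluded from training so near-OOD responses cannot
  # leak into the train distribution
  list(train = train, id_test = id_test, ood_test = sort(ood_test),
       excluded = sort(setdiff(in_ood, ood_test)),
       cluster = km$cluster, ood_cluster = ood_cluster)
}

#' Representational similarity analysis across response sets
#'
#' Builds one representational similarity matrix (RSM: images x images
#' Pearson correlation of multivariate patterns) per response set
#' (participant/ROI), then correlates every pair of RSMs over their strict
#' lower triangles.
#'
#' @param response_sets Named list of images x vertices matrices
#'   (trial-averaged), all with the same image rows.
#' @return A list with `rsms` (list of RSMs) and `scores` (sets x sets
#'   matrix of pairwise RSA scores; `NA` where an RSM is constant).
#' @export
rsa_compare <- function(response_sets) {
  stopifnot(is.list(response_sets), length(response_sets) >= 1L)
  n_img <- nrow(response_sets[[1]])
  if (n_img < 3L) stop("need at least 3 images")
  rsms <- lapply(response_sets, function(X) stats::cor(t(as.matrix(X))))
  lt <- lower.tri(rsms[[1]])
  vecs <- vapply(rsms, function(M) M[lt], numeric(sum(lt)))
  m <- length(rsms)
  scores <- matrix(NA_real_, m, m, dimnames = list(names(response_sets),
                                                   names(response_sets)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    vi <- vecs[, i]; vj <- vecs[, j]
    if (stats::sd(vi) > 0 && stats::sd(vj) > 0)
      scores[i, j] <- stats::cor(vi, vj)
  }
  list(rsms = rsms, scores = scores)
}

#' Distance-versus-performance statistic
#'
#' Correlates (Spearman, average ranks on ties) per-class distributional
#' distances with per-class model performance within each participant,
#' then tests the participant rho values against zero with a one-sample,
#' one-sided t-test in the configured direction.
#'
#' @param distances Per-class distances: either a single named vector
#'   (shared across participants) or a participants x classes matrix.
#' @param performance Participants x classes matrix of per-class scores
#'   (e.g. mean normalized explained variance, or mean identification
#'   rank).
#' @param alternative Direction of the test on the mean rho: `"less"`
#'   (anticorrelation expected, e.g. accuracy vs distance) or
#'   `"greater"` (e.g. rank vs distance).
#' @return A list with `rho` (per participant), `t`, `p`, `mean_rho`.
#' @export
distance_performance_stat <- function(distances, performance,
                                      alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  performance <- as.matrix(performance)
  if (ncol(performance) < 3L) stop("need at least 3 classes")
  if (nrow(performance) < 2L) stop("need at least 2 participants")
  if (is.vector(distances) || (is.matrix(distances) && nrow(distances) == 1L)) {
    distances <- matrix(rep(as.numeric(distances), each = nrow(performance)),
                        nrow(performance))
  }
  stopifnot(all(dim(distances) == dim(performance)))
  rho <- vapply(seq_len(nrow(performance)), function(i)
    stats::cor(distances[i, ], performance[i, ], method = "spearman"),
    numeric(1))
  if (stats::sd(rho) == 0) {
    # all participants identical: the t statistic degenerates; report the
    # limiting p-value for the configured direction
    in_dir <- (alternative == "less" && mean(rho) < 0) ||
      (alternative == "greater" && mean(rho) > 0)
    t_stat <- if (mean(rho) == 0) NaN else sign(mean(rho)) * Inf
    p <- if (mean(rho) == 0) 1 else if (in_dir) 0 else 1
  } else {
    ht <- stats::t.test(rho, mu = 0, alternative = alternative)
    t_stat <- unname(ht$statistic); p <- ht$p.value
  }
  list(rho = rho, t = t_stat, p = p, mean_rho = mean(rho))
}

#' Univariate subclass-by-ROI response profile
#'
#' The univariate averaging chain: responses are averaged first across
#' repeated trials of the same image, then across the vertices of each
#' ROI, then across the images of each subclass, and finally across
#' participants.
#'
#' @param responses List (one per participant) of `response_matrix`
#'   objects.
#' @param roi_of Vertex ROI label vector (shared across participants).
#' @param subclass_of Image subclass label per image index.
#' @return Matrix subclasses x ROIs of mean responses.
#' @export
univariate_profile <- function(responses, roi_of, subclass_of) {
  per_part <- lapply(responses, function(rm) {
    stopifnot(inherits(rm, "response_matrix"))
    imgs <- sort(unique(rm$trial_image))
    avg <- t(vapply(imgs, function(im)
      colMeans(rm$betas[rm$trial_image == im, , drop = FALSE]),
      numeric(ncol(rm$betas))))                      # images x vertices
    rois <- unique(roi_of)
    roi_means <- vapply(rois, function(r)
      rowMeans(avg[, roi_of == r, drop = FALSE]), numeric(nrow(avg)))
    sub <- subclass_of[imgs]
    out <- apply(roi_means, 2, function(v) tapply(v, sub, mean))
    out
  })
  Reduce(`+`, per_part) / length(per_part)
}
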