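#' Response matrix container
#'
#' Holds single-trial response amplitude estimates ("betas") as a trials x
#' vertices matrix together with per-trial labels: the image shown, the
#' session the trial came from, and the task performed.
#'
#' @param betas Numeric matrix, trials x vertices, finite.
#' @param trial_image Integer image index per trial.
#' @param trial_session Session label per trial (defaults to one session).
#' @param trial_task Task label per trial (optional).
#' @return A `response_matrix` object.
#' @export
response_matrix <- function(betas, trial_image, trial_session = NULL,
                            trial_task = NULL) {
  stopifnot(is.matrix(betas), all(is.finite(betas)),
            length(trial_image) == nrow(betas))
  if (is.null(trial_session)) trial_session <- rep(1L, nrow(betas))
  stopifnot(length(trial_session) == nrow(betas))
  if (!is.null(trial_task)) stopifnot(length(trial_task) == nrow(betas))
  structure(list(betas = betas, trial_image = trial_image,
                 trial_session = trial_session, trial_task = trial_task),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response matrix: %d trials x %d vertices, %d images, %d session(s)\n",
              nrow(x$betas), ncol(x$betas), length(unique(x$trial_image)),
              length(unique(x$trial_session))))
  invisible(x)
}

# z-score each vertex within each session (the convention of the adopted
# noise-ceiling method; note that z-scoring also rescales genuine signal,
# so it is switchable)
zscore_by_session <- function(betas, session) {
  for (s in unique(session)) {
    i <- session == s
    m <- colMeans(betas[i, , drop = FALSE])
    sd <- apply(betas[i, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    betas[i, ] <- sweep(sweep(betas[i, , drop = FALSE], 2, m), 2, sd, "/")
  }
  betas
}

#' Noise ceiling signal-to-noise ratio (NCSNR)
#'
#' Estimates, per vertex, the ratio of stimulus-driven signal SD to trial
#' noise SD from repeated presentations. The noise variance is the mean,
#' over images with at least two repeats, of the unbiased variance across
#' repeats; the signal variance is the total variance across all trials
#' minus the noise variance, floored at zero. Betas are z-scored per
#' session per vertex first (switchable with `zscore`).
#'
#' @param responses A `response_matrix` (or a plain betas matrix together
#'   with `trial_image`).
#' @param trial_image Image index per trial when `responses` is a matrix.
#' @param zscore Whether to z-score per session before estimating.
#' @return Numeric vector of per-vertex NCSNR values (>= 0), with
#'   attribute `n_images_used` (images contributing repeat variance).
#' @export
compute_ncsnr <- function(responses, trial_image = NULL, zscore = TRUE) {
  if (inherits(responses, "response_matrix")) {
    betas <- responses$betas
    trial_image <- responses$trial_image
    session <- responses$trial_session
  } else {
    betas <- responses
    if (is.null(trial_image)) stop("trial_image required for a plain matrix")
    session <- rep(1L, nrow(betas))
  }
  if (zscore) betas <- zscore_by_session(betas, session)
  reps <- table(trial_image)
  rep_images <- names(reps)[reps >= 2L]
  if (length(rep_images) == 0L)
    stop("no image with >= 2 repeats; noise variance is not estimable")
  noise_var <- matrix(0, length(rep_images), ncol(betas))
  for (j in seq_along(rep_images)) {
    i <- trial_image == rep_images[j]
    noise_var[j, ] <- apply(betas[i, , drop = FALSE], 2, stats::var)
  }
  sigma_noise2 <- colMeans(noise_var)
  sigma_total2 <- apply(betas, 2, stats::var)
  sigma_signal2 <- pmax(0, sigma_total2 - sigma_noise2)
  s <- ifelse(sigma_noise2 > 0, sqrt(sigma_signal2) / sqrt(sigma_noise2), 0)
  s[sigma_noise2 == 0 & sigma_signal2 > 0] <- Inf
  attr(s, "n_images_used") <- length(rep_images)
  s
}

#' Convert NCSNR to a noise-ceiling variance fraction
#'
#' `NC = 100 * s^2 / (s^2 + 1/n)`: the percentage of variance in responses
#' averaged over `n` repeats that is attributable to stimulus-driven
#' signal. At `n = 1` (single-trial responses), NCSNR 2 gives 80%, 0.75
#' gives 36%, and 0.5 gives 20%.
#'
#' @param s NCSNR value(s), >= 0.
#' @param n_repeats Number of averaged repeats (may be fractional, e.g. a
#'   harmonic mean over images with unequal repeat counts).
#' @return Noise ceiling in percent, in [0, 100].
#' @export
ncsnr_to_noise_ceiling <- function(s, n_repeats = 1) {
  stopifnot(all(s >= 0), all(n_repeats >= 0), any(n_repeats > 0) || length(n_repeats) == 0)
  100 * s^2 / (s^2 + 1 / n_repeats)
}

#' Effective repeat count for mixed repeat designs
#'
#' Harmonic-mean rule: `n_eff = 1 / mean(1 / n_i)` over the per-image
#' repeat counts of the test set, the conventional treatment when images
#' have unequal numbers of presentations.
#'
#' @param n_per_image Integer vector of repeats per image (>= 1).
#' @return Effective n.
#' @export
effective_repeats <- function(n_per_image) {
  stopifnot(all(n_per_image >= 1))
  1 / mean(1 / n_per_image)
}

#' Threshold vertices on reliability
#'
#' Strict comparison: a vertex passes when its score exceeds the
#' threshold. Used both for NCSNR thresholds (e.g. 0.6) and for
#' noise-ceiling-fraction rules (e.g. noise ceiling above 0.3).
#'
#' @param scores Per-vertex scores.
#' @param threshold Threshold value.
#' @return Logical mask.
#' @export
select_vertices <- function(scores, threshold) {
  as.logical(scores > threshold)
}
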