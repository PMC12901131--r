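#' Simulate beta-like responses with known ground truth
#'
#' Generates trials x vertices response amplitudes from a linear tuning
#' model: each vertex responds as a random linear readout of the stimulus
#' features, standardized across images and scaled to a target signal SD,
#' plus an additive per-session offset and i.i.d. Gaussian trial noise.
#' With unit noise SD (the default), the per-vertex signal SD equals the
#' vertex's true noise ceiling signal-to-noise ratio. Designated
#' out-of-distribution classes can have their signal rotated towards an
#' independent off-readout component: at rotation angle `a`, the simulated
#' signal is `cos(a) * in-model + sin(a) * off-model`, so `a = 0` is fully
#' in-distribution and `a = pi/2` is orthogonal to the trained readout
#' while preserving signal strength.
#'
#' @param features Images x features matrix (e.g. from
#'   [extract_features()], or any numeric design).
#' @param n_vertices Number of simulated vertices.
#' @param ncsnr Target signal SD per vertex (scalar or length
#'   `n_vertices`); equals the true NCSNR when `noise_sd = 1`.
#' @param repeats Presentations per image per task.
#' @param tasks Task labels; trials are replicated per task.
#' @param n_sessions Number of sessions; trials are split evenly across
#'   sessions in order.
#' @param session_offset_sd SD of the per-session, per-vertex additive
#'   offset.
#' @param noise_sd Trial noise SD (0 allowed for noise-free data).
#' @param class_of Optional per-image class labels (for OOD perturbation).
#' @param ood_rotation Optional named numeric vector of rotation angles
#'   (radians) per class; classes not named get 0.
#' @param ood_shift Optional named numeric vector per class: magnitude of
#'   an additive off-manifold component, in units of the mean per-vertex
#'   signal SD. Each named class gets a fixed random vertex pattern added
#'   to its signal, displacing the class's response distribution away
#'   from the training manifold by the given amount.
#' @param seed Integer seed.
#' @return A list with `responses` (a [response_matrix()]) and `truth`
#'   (list: `weights`, `signal` images x vertices noiseless tuning,
#'   `signal_sd`, `noise_sd`, `ood_rotation`, `session_offsets`).
#' @export
simulate_responses <- function(features, n_vertices = 100L, ncsnr = 1,
                               repeats = 3L, tasks = "FIXATION",
                               n_sessions = 1L, session_offset_sd = 0,
                               noise_sd = 1, class_of = NULL,
                               ood_rotation = NULL, ood_shift = NULL,
                               seed = 1L) {
  X <- as.matrix(features)
  n_img <- nrow(X); p <- ncol(X)
  signal_sd <- rep_len(ncsnr, n_vertices)
  if (any(signal_sd < 0) || noise_sd < 0 || session_offset_sd < 0)
    stop("SDs must be non-negative")
  if (noise_sd == 0 && all(signal_sd == 0))
    stop("zero signal and zero noise: responses would be constant")
  with_seed(seed, {
    W <- matrix(stats::rnorm(p * n_vertices), p, n_vertices)
    standardize <- function(S) {
      S <- sweep(S, 2, colMeans(S))
      sds <- apply(S, 2, stats::sd)
      sds[sds == 0] <- 1
      sweep(S, 2, sds, "/")
    }
    signal <- standardize(X %*% W)
    if (!is.null(ood_rotation)) {
      stopifnot(!is.null(class_of), length(class_of) == n_img)
      W_off <- matrix(stats::rnorm(p * n_vertices), p, n_vertices)
      off <- standardize(matrix(stats::rnorm(n_img * n_vertices),
                                n_img, n_vertices))
      for (cl in names(ood_rotation)) {
        a <- ood_rotation[[cl]]
        i <- class_of == cl
        signal[i, ] <- cos(a) * signal[i, ] + sin(a) * off[i, ]
      }
    }
    signal <- sweep(signal, 2, signal_sd, "*")
    if (!is.null(ood_shift)) {
      stopifnot(!is.null(class_of), length(class_of) == n_img)
      for (cl in names(ood_shift)) {
        u <- stats::rnorm(n_vertices)
        u <- u / sqrt(sum(u^2)) * sqrt(n_vertices)   # unit RMS per vertex
        i <- class_of == cl
        signal[i, ] <- signal[i, ] +
          rep(ood_shift[[cl]] * mean(signal_sd) * u, each = sum(i))
      }
    }

    trial_image <- rep(rep(seq_len(n_img), times = repeats), times = length(tasks))
    n_trials <- length(trial_image)
    trial_task <- rep(tasks, each = n_img * repeats)
    trial_session <- rep_len(rep(seq_len(n_sessions),
                                 each = ceiling(n_trials / n_sessions)), n_trials)
    offsets <- matrix(stats::rnorm(n_sessions * n_vertices,
                                   sd = session_offset_sd),
                      n_sessions, n_vertices)
    betas <- signal[trial_image, , drop = FALSE] +
      offsets[trial_session, , drop = FALSE] +
      matrix(stats::rnorm(n_trials * n_vertices, sd = noise_sd),
             n_trials, n_vertices)
    list(responses = response_matrix(betas, trial_image, trial_session,
                                     trial_task),
         truth = list(weights = W, signal = signal, signal_sd = signal_sd,
                      noise_sd = noise_sd, ood_rotation = ood_rotation,
                      ood_shift = ood_shift, session_offsets = offsets))
  })
}

#' Trial-average a response matrix per image
#'
#' @param responses A `response_matrix`.
#' @param images Image indices to keep (default: all, sorted).
#' @return Images x vertices matrix of repeat-averaged responses, with
#'   rownames set to the image indices.
#' @export
average_by_image <- function(responses, images = sort(unique(responses$trial_image))) {
  out <- t(vapply(images, function(im)
    colMeans(responses$betas[responses$trial_image == im, , drop = FALSE]),
    numeric(ncol(responses$betas))))
  rownames(out) <- images
  out
}
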