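#' Prepare an image raster for feature extraction
#'
#' Applies the standard model-input pipeline: center crop to a square of
#' the short side, bilinear resize to 224 x 224, optional elementwise
#' square-root transform (used for luminance-coded synthetic images so
#' their intensity statistics match gamma-encoded photographs), scaling to
#' [0, 1], channel replication for grayscale inputs, and channelwise
#' standardization with mean (0.485, 0.456, 0.406) and SD
#' (0.229, 0.224, 0.225).
#'
#' @param image A `luminance_image`, a matrix, or an RGB array in [0, 1].
#' @param sqrt_transform Apply the square-root transform.
#' @param size Output side in pixels.
#' @return A `size` x `size` x 3 standardized array.
#' @export
preprocess_image <- function(image, sqrt_transform = FALSE, size = 224L) {
  if (inherits(image, "luminance_image")) {
    if (image$chromatic) {
      arr <- lut_export_rgb(image)
    } else {
      arr <- as_canvas(image)
    }
  } else arr <- image
  to_square <- function(m) {
    short <- min(dim(m)[1:2])
    r0 <- (dim(m)[1] - short) %/% 2L
    c0 <- (dim(m)[2] - short) %/% 2L
    m[(r0 + 1L):(r0 + short), (c0 + 1L):(c0 + short)]
  }
  if (is.matrix(arr)) {
    ch <- list(to_square(arr))
    ch <- rep(ch, 3L)
  } else {
    ch <- lapply(1:3, function(k) to_square(arr[, , k]))
  }
  ch <- lapply(ch, function(m)
    as.matrix(EBImage::resize(EBImage::Image(m), w = size, h = size)))
  if (sqrt_transform) ch <- lapply(ch, function(m) sqrt(pmax(m, 0)))
  mx <- max(unlist(lapply(ch, max)), 1)
  ch <- lapply(ch, function(m) { m <- m / mx; m[m < 0] <- 0; m[m > 1] <- 1; m })
  means <- c(0.485, 0.456, 0.406); sds <- c(0.229, 0.224, 0.225)
  out <- array(0, c(size, size, 3L))
  for (k in 1:3) out[, , k] <- (ch[[k]] - means[k]) / sds[k]
  out
}

#' Feature extractor contract
#'
#' An extractor is a named callable mapping an image to per-layer numeric
#' feature vectors; it must be deterministic with fixed output
#' dimensionality. `feature_extractor()` wraps a function into the
#' contract; [oriented_energy_extractor()] builds the packaged default, a
#' weight-free multiscale oriented-energy filter bank (quadrature log-Gabor
#' energy pooled on a coarse grid), so the whole pipeline runs without
#' pretrained network weights.
#'
#' @param name Extractor name.
#' @param layers Character vector of layer labels.
#' @param fn Function(image) -> named list of numeric vectors, one per
#'   layer.
#' @return A `feature_extractor` object (callable via [extract_features()]).
#' @export
feature_extractor <- function(name, layers, fn) {
  structure(list(name = name, layers = layers, fn = fn),
            class = "feature_extractor")
}

# one-sided log-Gabor filter bank in the frequency domain for an n x n grid
log_gabor_bank <- function(n, wavelengths, n_orient) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fx <- matrix(rep(f, each = n), n, n)
  fy <- matrix(rep(f, times = n), n, n)
  rad <- sqrt(fx^2 + fy^2); rad[1, 1] <- 1
  ang <- atan2(fy, fx)
  sigma_r <- 0.65; sigma_a <- 0.6
  bank <- list()
  for (w in wavelengths) {
    f0 <- 1 / w
    radial <- exp(-(log(rad / f0))^2 / (2 * log(sigma_r)^2))
    radial[1, 1] <- 0
    for (o in seq_len(n_orient)) {
      theta <- (o - 1) * pi / n_orient
      d <- atan2(sin(ang - theta), cos(ang - theta))
      angular <- exp(-d^2 / (2 * sigma_a^2)) # one-sided: kills -theta lobe
      bank[[sprintf("w%g_o%d", w, o)]] <- radial * angular
    }
  }
  bank
}

# mean-pool a matrix onto a grid x grid array of cell averages
pool_grid <- function(m, grid) {
  n <- nrow(m)
  idx <- ceiling(seq_len(n) / n * grid)
  rs <- rowsum(m, idx)
  t(rowsum(t(rs), idx)) / (n / grid)^2
}

#' @rdname feature_extractor
#' @param wavelengths Filter center wavelengths in pixels (one "layer" per
#'   scale).
#' @param n_orient Number of orientations.
#' @param grid Pooling grid side; each layer has `n_orient * grid^2`
#'   features.
#' @param size Expected input side in pixels.
#' @export
oriented_energy_extractor <- function(wavelengths = c(4, 8, 16, 32),
                                      n_orient = 4L, grid = 7L, size = 224L) {
  bank <- log_gabor_bank(size, wavelengths, n_orient)
  layer_names <- paste0("scale", seq_along(wavelengths))
  fn <- function(image) {
    arr <- if (is.matrix(image)) image else
      if (length(dim(image)) == 3L) (image[, , 1] + image[, , 2] + image[, , 3]) / 3
      else stop("image must be a matrix or 3-d array")
    if (!all(dim(arr) == c(size, size)))
      arr <- as.matrix(EBImage::resize(EBImage::Image(arr), w = size, h = size))
    FT <- stats::fft(arr)
    out <- vector("list", length(wavelengths))
    names(out) <- layer_names
    for (s in seq_along(wavelengths)) {
      feats <- numeric(0)
      for (o in seq_len(n_orient)) {
        filt <- bank[[(s - 1L) * n_orient + o]]
        resp <- stats::fft(FT * filt, inverse = TRUE) / (size * size)
        energy <- Mod(resp)   # quadrature-pair energy via the analytic filter
        feats <- c(feats, as.vector(pool_grid(energy, grid)))
      }
      out[[s]] <- feats
    }
    out
  }
  feature_extractor("oriented-energy", layer_names, fn)
}

#' Extract features for a set of images
#'
#' Runs the extractor on each image (after [preprocess_image()] when given
#' `luminance_image`s) and concatenates the requested layers into a
#' feature matrix.
#'
#' @param images List of images (any form accepted by the extractor after
#'   preprocessing), or a `stimulus_set`.
#' @param extractor A `feature_extractor`.
#' @param layers Layers to concatenate (default all).
#' @param sqrt_transform Passed to [preprocess_image()] for
#'   `luminance_image` inputs.
#' @return Numeric matrix, images x features.
#' @export
extract_features <- function(images, extractor = oriented_energy_extractor(),
                             layers = extractor$layers, sqrt_transform = TRUE) {
  if (inherits(images, "stimulus_set")) images <- images$images
  rows <- lapply(images, function(im) {
    if (inherits(im, "luminance_image"))
      im <- preprocess_image(im, sqrt_transform = sqrt_transform)
    per_layer <- extractor$fn(im)
    unlist(per_layer[layers], use.names = FALSE)
  })
  do.call(rbind, rows)
}
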