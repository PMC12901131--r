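#' Prepare a photographic scene for presentation
#'
#' Applies, in order: grayscale conversion (Rec. 709 luma for RGB inputs),
#' center square crop, resize to the central-square resolution (714 x 714
#' by default, bilinear), display-gamma conversion (`value^2` on [0, 1]
#' gray), and contrast normalization mapping the 0.1 and 99.9 percentiles
#' linearly onto [0, 1] (values outside are clipped and the clipped
#' fraction recorded).
#'
#' @param raw Numeric matrix (grayscale) or 3-d array (RGB, third dim = 3)
#'   with values in [0, 1].
#' @param geometry A `display_geometry`.
#' @return A `luminance_image`.
#' @export
prep_scene <- function(raw, geometry = display_geometry()) {
  if (length(raw) == 0) stop("empty input image")
  if (is.array(raw) && length(dim(raw)) == 3L) {
    if (dim(raw)[3] < 3L) stop("color input must have 3 channels")
    gray <- 0.2126 * raw[, , 1] + 0.7152 * raw[, , 2] + 0.0722 * raw[, , 3]
  } else if (is.matrix(raw)) {
    gray <- raw
  } else stop("raw must be a matrix or a 3-d array")
  side_out <- geometry$square_px
  short <- min(dim(gray))
  if (short < side_out)
    message(sprintf("input short side %d px < %d px; upsampling", short, side_out))
  # center square crop
  r0 <- (nrow(gray) - short) %/% 2L
  c0 <- (ncol(gray) - short) %/% 2L
  sq <- gray[(r0 + 1L):(r0 + short), (c0 + 1L):(c0 + short), drop = FALSE]
  if (short != side_out)
    sq <- as.matrix(EBImage::resize(EBImage::Image(sq), w = side_out, h = side_out))
  sq[sq < 0] <- 0; sq[sq > 1] <- 1
  lum <- sq^2.0   # display gamma 2.0
  q <- stats::quantile(lum, c(0.001, 0.999), names = FALSE)
  if (q[2] - q[1] <= .Machine$double.eps)
    stop("degenerate contrast normalization: 0.1 and 99.9 percentiles are equal")
  cl <- clip01((lum - q[1]) / (q[2] - q[1]))
  luminance_image(cl$values, geometry, clip_fraction = cl$clip_fraction)
}

#' Rotate a prepared scene by 180 degrees
#' @param image A `luminance_image`.
#' @return A `luminance_image`.
#' @export
upside_down <- function(image) {
  v <- image$values
  out <- v[rev(seq_len(nrow(v))), rev(seq_len(ncol(v))), drop = FALSE]
  luminance_image(out, image$geometry, region = image$region)
}

#' Mooney (median-binarized) version of a prepared scene
#'
#' Thresholds at the median pixel value: pixels at or above the median map
#' to white (1), pixels below to black (0). The "at or above" tie rule
#' makes the operator deterministic and idempotent.
#'
#' @param image A `luminance_image` (typically from [prep_scene()]).
#' @return A binary `luminance_image` (values in {0, 1}).
#' @export
mooney <- function(image) {
  m <- stats::median(image$values)
  out <- matrix(as.numeric(image$values >= m), nrow(image$values), ncol(image$values))
  luminance_image(out, image$geometry, region = image$region)
}

#' Scale image contrast towards mid-gray
#'
#' Treats the input as 100% contrast and returns
#' `0.5 + c * (values - 0.5)`. Composable: applying with `a` then `b`
#' equals applying once with `a * b`.
#'
#' @param image A `luminance_image` with values in [0, 1].
#' @param c Contrast fraction in (0, 1].
#' @return A `luminance_image`.
#' @export
contrast_modulate <- function(image, c) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c > 1)
    stop("contrast level c must be in (0, 1]")
  luminance_image(0.5 + c * (image$values - 0.5), image$geometry,
                  region = image$region)
}

#' Blend an image's Fourier phase with a random phase spectrum
#'
#' Retains the amplitude spectrum exactly and interpolates each frequency's
#' phase circularly (shortest arc) between the original phase (weight `k`)
#' and a random phase drawn from the Fourier transform of white noise
#' (which guarantees Hermitian symmetry, hence a real-valued result).
#' Self-conjugate frequency bins (DC and Nyquist) keep their original
#' phase. The inverse transform is finally clipped to [0, 1]; the clipped
#' fraction is recorded on the returned image.
#'
#' @param image A `luminance_image` (values in [0, 1]).
#' @param k Phase-coherence fraction in [0, 1]: `k = 1` returns the input,
#'   `k = 0` fully randomizes phase while preserving amplitudes.
#' @param rng_seed Integer seed for the random phase spectrum.
#' @return A `luminance_image`.
#' @export
phase_coherence_blend <- function(image, k, rng_seed = 1L) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 1)
    stop("coherence k must be in [0, 1]")
  v <- image$values
  n1 <- nrow(v); n2 <- ncol(v)
  Z <- stats::fft(v)
  noise <- with_seed(rng_seed, matrix(stats::rnorm(n1 * n2), n1, n2))
  R <- stats::fft(noise)
  # shortest-arc phase step from original towards random, scaled by (1 - k);
  # Arg(R * Conj(Z)) is antisymmetric for Hermitian Z, R, so realness holds
  delta <- Arg(R * Conj(Z))
  # keep self-conjugate bins (where phases are 0 or pi) at original phase
  sc_r <- unique(c(1L, if (n1 %% 2L == 0L) n1 %/% 2L + 1L))
  sc_c <- unique(c(1L, if (n2 %% 2L == 0L) n2 %/% 2L + 1L))
  delta[sc_r, sc_c] <- 0
  Zb <- Z * exp(1i * (1 - k) * delta)
  out <- Re(stats::fft(Zb, inverse = TRUE)) / (n1 * n2)
  cl <- clip01(out)
  luminance_image(cl$values, image$geometry, region = image$region,
                  clip_fraction = cl$clip_fraction)
}

#' Edge-map line-drawing substitute
#'
#' Stands in for artist-traced line drawings of the scene photographs:
#' Sobel gradient magnitude of the prepared scene, thresholded at a high
#' quantile, rendered as black strokes (0) on a gray background (0.5).
#' Labeled a substitute wherever it appears in the stimulus registry.
#'
#' @param image A prepared `luminance_image`.
#' @param edge_quantile Quantile of gradient magnitude above which a pixel
#'   becomes a stroke.
#' @return A `luminance_image` with values in {0, 0.5}.
#' @export
line_drawing_substitute <- function(image, edge_quantile = 0.9) {
  v <- image$values
  n1 <- nrow(v); n2 <- ncol(v)
  pad <- rbind(v[1, , drop = FALSE], v, v[n1, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, n2, drop = FALSE])
  i <- 2:(n1 + 1); j <- 2:(n2 + 1)
  gx <- (pad[i - 1, j + 1] + 2 * pad[i, j + 1] + pad[i + 1, j + 1]) -
        (pad[i - 1, j - 1] + 2 * pad[i, j - 1] + pad[i + 1, j - 1])
  gy <- (pad[i + 1, j - 1] + 2 * pad[i + 1, j] + pad[i + 1, j + 1]) -
        (pad[i - 1, j - 1] + 2 * pad[i - 1, j] + pad[i - 1, j + 1])
  mag <- sqrt(gx^2 + gy^2)
  thr <- stats::quantile(mag, edge_quantile, names = FALSE)
  out <- matrix(0.5, n1, n2)
  out[mag > thr] <- 0
  luminance_image(out, image$geometry, region = image$region)
}

#' Procedural scene-like fixture images
#'
#' Generates deterministic scene-like raster images: a 1/f textured
#' background overlaid with a handful of geometric occluders (rectangles
#' and ellipses at distinct gray levels, lightly textured), loosely
#' emulating the layout statistics of photographs. These serve as inputs
#' to [prep_scene()] when no user-supplied photographs are given, and as a
#' stand-in pool of naturalistic images for simulation studies.
#'
#' @param n Number of images.
#' @param seed Integer seed; output is bit-identical per seed.
#' @param side Image side in pixels.
#' @return A list of `n` matrices with values in [0, 1].
#' @export
make_naturalistic_fixtures <- function(n, seed = 1L, side = 714L) {
  if (n < 1) stop("n must be >= 1")
  amp <- 1 / radial_freq(side)
  amp[1, 1] <- 0
  lapply(seq_len(n), function(i) {
    with_seed(child_seed(seed, i), {
      white <- matrix(stats::rnorm(side * side), side, side)
      bg <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (side * side)
      bg <- (bg - mean(bg)) / (6 * stats::sd(bg)) + 0.5
      xs <- matrix(rep(seq_len(side), each = side), side, side)
      ys <- matrix(rep(seq_len(side), times = side), side, side)
      n_obj <- sample(3:6, 1)
      for (o in seq_len(n_obj)) {
        cx <- stats::runif(1, 0.15, 0.85) * side
        cy <- stats::runif(1, 0.15, 0.85) * side
        rx <- stats::runif(1, 0.05, 0.25) * side
        ry <- stats::runif(1, 0.05, 0.25) * side
        lev <- stats::runif(1, 0.1, 0.9)
        tex <- stats::runif(1, 0.02, 0.08)
        if (stats::runif(1) < 0.5) {
          mask <- abs(xs - cx) < rx & abs(ys - cy) < ry
        } else {
          mask <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 < 1
        }
        bg[mask] <- lev + tex * (bg[mask] - 0.5) / 0.5
      }
      bg[bg < 0] <- 0; bg[bg > 1] <- 1
      bg
    })
  })
}
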