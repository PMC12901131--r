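#' White-noise stimulus
#'
#' Fills the central square with blockwise i.i.d. Uniform(0, 1) luminance.
#' `block_px = 1` gives per-pixel white noise; `block_px = 42` gives the
#' large-block variant (17 full 42-px blocks tile the 714-px square exactly).
#' For block sizes that do not divide the square, partial edge blocks get
#' their own independent draw.
#'
#' @param geometry A `display_geometry`.
#' @param block_px Block side in pixels (>= 1).
#' @param rng_seed Integer seed; equal seeds give bit-identical images.
#' @return A `luminance_image`.
#' @export
make_white_noise <- function(geometry = display_geometry(), block_px = 1L,
                             rng_seed = 1L) {
  block_px <- as.integer(block_px)
  if (is.na(block_px) || block_px < 1L) stop("block_px must be a positive integer")
  side <- geometry$square_px
  n_blocks <- ceiling(side / block_px)
  draws <- with_seed(rng_seed,
                     matrix(stats::runif(n_blocks * n_blocks), n_blocks, n_blocks))
  idx <- rep(seq_len(n_blocks), each = block_px, length.out = side)
  vals <- draws[idx, idx, drop = FALSE]
  luminance_image(vals, geometry)
}

# radial spatial-frequency map (cycles/image) for an n x n FFT grid,
# frequencies in fftfreq layout
radial_freq <- function(n) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # integer cycles per image
  fx <- matrix(rep(f, each = n), n, n)
  fy <- matrix(rep(f, times = n), n, n)
  sqrt(fx^2 + fy^2)
}

#' Pink-noise (1/f) stimulus
#'
#' Multiplies the Fourier transform of white Gaussian noise by a 1/f
#' amplitude spectrum, inverts, and maps the range mean +/- `clip_sd`
#' standard deviations linearly onto [0, 1] (values beyond are clipped; the
#' clipped fraction is recorded). The DC amplitude is set to zero before
#' inversion so the image is centered on mid-gray. `contrast_scale`
#' optionally scales the result towards 0.5 afterwards (used for the
#' reduced-contrast achromatic base patterns of the chromatic-noise class).
#'
#' @param geometry A `display_geometry`.
#' @param rng_seed Integer seed.
#' @param clip_sd Number of standard deviations mapped to the full range.
#' @param contrast_scale Optional factor in [0, 1] applied towards 0.5.
#' @return A `luminance_image`.
#' @export
make_pink_noise <- function(geometry = display_geometry(), rng_seed = 1L,
                            clip_sd = 3.5, contrast_scale = NULL) {
  if (clip_sd <= 0) stop("clip_sd must be positive")
  side <- geometry$square_px
  if (side %% 2L != 0L) stop("central square side must be even")
  white <- with_seed(rng_seed, matrix(stats::rnorm(side * side), side, side))
  amp <- 1 / radial_freq(side)
  amp[1, 1] <- 0 # DC removed; image centered on mid-gray by the mapping below
  shaped <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (side * side)
  z <- (shaped - mean(shaped)) / stats::sd(shaped)   # zero mean, unit SD
  vals <- (z + clip_sd) / (2 * clip_sd)              # +/- clip_sd -> [0, 1]
  cl <- clip01(vals)
  vals <- cl$values
  if (!is.null(contrast_scale)) {
    if (contrast_scale < 0 || contrast_scale > 1)
      stop("contrast_scale must be in [0, 1]")
    vals <- 0.5 + contrast_scale * (vals - 0.5)
  }
  luminance_image(vals, geometry, clip_fraction = cl$clip_fraction)
}

#' Isoluminant chromatic-noise stimulus
#'
#' Builds an isoluminant image whose luminance channel is constant at the
#' gray point (0.5) and whose two opponent chroma channels modulate along a
#' single hue direction of a hue circle. Hue angles are evenly spaced:
#' hue `h` sits at angle `2*pi*(h-1)/16`, so hues 1 and 9 are antiparallel.
#' Saturation at each pixel is proportional to the (reduced-contrast)
#' achromatic base pattern, scaled to peak at `gamut_radius` — the radius
#' of the largest hue circle that fits in the display gamut. The opponent
#' plane here is a generic hue circle, not a colorimetrically calibrated
#' cone-opponent space.
#'
#' @param geometry A `display_geometry`.
#' @param hue_index Integer 1..16 selecting the hue angle.
#' @param base_pattern A `luminance_image` (achromatic) whose values in
#'   [0, 1] set the per-pixel saturation.
#' @param gamut_radius Maximum chroma magnitude (> 0).
#' @return A chromatic `luminance_image`.
#' @export
make_chromatic_noise <- function(geometry = display_geometry(), hue_index,
                                 base_pattern, gamut_radius = 0.35) {
  hue_index <- as.integer(hue_index)
  if (is.na(hue_index) || hue_index < 1L || hue_index > 16L)
    stop("hue_index must be in 1..16")
  if (gamut_radius <= 0) stop("gamut_radius must be positive")
  stopifnot(inherits(base_pattern, "luminance_image"))
  angle <- 2 * pi * (hue_index - 1L) / 16
  sat <- base_pattern$values * gamut_radius
  lum <- matrix(0.5, nrow(sat), ncol(sat))
  luminance_image(lum, geometry, region = base_pattern$region,
                  chroma = list(sat * cos(angle), sat * sin(angle)))
}
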