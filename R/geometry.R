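#' Display geometry
#'
#' Anchors all degree/pixel conversions for stimulus synthesis. The default
#' geometry is a 1360 x 714 pixel canvas spanning 16 x 8.4 degrees of visual
#' angle, i.e. 85 pixels per degree. The central square region (714 x 714
#' pixels, horizontally centered) is where most stimulus content lives; the
#' left/right flanks are filled with the mid-gray background (0.5).
#'
#' @param canvas_w,canvas_h Canvas size in pixels.
#' @param field_w,field_h Visual-field extent in degrees.
#' @param tol Relative tolerance on the consistency of the two
#'   pixels-per-degree estimates implied by width and height.
#' @return An object of class `display_geometry` with fields `canvas_w`,
#'   `canvas_h`, `field_w`, `field_h`, `ppd` (pixels per degree) and
#'   `square_px` (side of the central square, equal to `canvas_h`).
#' @examples
#' geom <- display_geometry()
#' geom$ppd            # 85
#' deg_to_px(geom, 6)  # 510
#' @export
display_geometry <- function(canvas_w = 1360L, canvas_h = 714L,
                             field_w = 16.0, field_h = 8.4, tol = 1e-6) {
  if (canvas_w <= 0 || canvas_h <= 0 || field_w <= 0 || field_h <= 0)
    stop("canvas and field dimensions must be positive")
  ppd_w <- canvas_w / field_w
  ppd_h <- canvas_h / field_h
  if (abs(ppd_w - ppd_h) / ppd_w > tol)
    stop(sprintf("inconsistent aspect ratio: %.6f px/deg (width) vs %.6f px/deg (height)",
                 ppd_w, ppd_h))
  structure(list(canvas_w = as.integer(canvas_w), canvas_h = as.integer(canvas_h),
                 field_w = field_w, field_h = field_h,
                 ppd = ppd_w, square_px = as.integer(canvas_h)),
            class = "display_geometry")
}

#' @rdname display_geometry
#' @param geometry A `display_geometry`.
#' @param deg Degrees of visual angle.
#' @export
deg_to_px <- function(geometry, deg) deg * geometry$ppd

#' @rdname display_geometry
#' @param px Pixels.
#' @export
px_to_deg <- function(geometry, px) px / geometry$ppd

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("display geometry: %d x %d px, %.1f x %.1f deg (%.2f px/deg)\n",
              x$canvas_w, x$canvas_h, x$field_w, x$field_h, x$ppd))
  invisible(x)
}

#' Luminance image container
#'
#' A stimulus image on a display geometry. Luminance values live in [0, 1]
#' (0 = black, 1 = white, 0.5 = background gray). Most stimuli occupy only
#' the central square of the canvas; to keep memory proportionate, the
#' container stores either the central square or, for stimuli whose content
#' extends into the flanks (peripheral words), the full canvas. Chromatic
#' images additionally carry two opponent chroma channels of the same size
#' as the luminance channel.
#'
#' @param values Numeric matrix of luminance in [0, 1] (rows = y, cols = x).
#' @param geometry A `display_geometry`.
#' @param region `"central"` if `values` covers only the central square,
#'   `"full"` if it covers the whole canvas.
#' @param chroma Optional list of two matrices (opponent chroma channels)
#'   matching `dim(values)`; implies a chromatic image.
#' @param clip_fraction Fraction of pixels clipped into [0, 1] during final
#'   preparation (kept for the record; clipping is never silent).
#' @return A `luminance_image` object.
#' @export
luminance_image <- function(values, geometry, region = c("central", "full"),
                            chroma = NULL, clip_fraction = 0) {
  region <- match.arg(region)
  stopifnot(is.matrix(values))
  expect_dim <- if (region == "central")
    c(geometry$square_px, geometry$square_px) else c(geometry$canvas_h, geometry$canvas_w)
  if (!all(dim(values) == expect_dim))
    stop(sprintf("values must be %d x %d for region '%s'",
                 expect_dim[1], expect_dim[2], region))
  if (any(!is.finite(values)) || min(values) < 0 || max(values) > 1)
    stop("luminance values must be finite and within [0, 1]")
  if (!is.null(chroma)) {
    stopifnot(is.list(chroma), length(chroma) == 2L,
              all(vapply(chroma, function(m) all(dim(m) == dim(values)), logical(1))))
  }
  structure(list(values = values, geometry = geometry, region = region,
                 chromatic = !is.null(chroma), chroma = chroma,
                 clip_fraction = clip_fraction),
            class = "luminance_image")
}

#' Paste an image onto the full canvas
#'
#' Returns the full `canvas_h` x `canvas_w` luminance matrix, with the
#' flanks at background gray (0.5) when the stored region is central.
#'
#' @param img A `luminance_image`.
#' @return A numeric matrix of size canvas_h x canvas_w.
#' @export
as_canvas <- function(img) {
  g <- img$geometry
  if (img$region == "full") return(img$values)
  out <- matrix(0.5, g$canvas_h, g$canvas_w)
  x0 <- (g$canvas_w - g$square_px) %/% 2L
  out[, (x0 + 1L):(x0 + g$square_px)] <- img$values
  out
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf("luminance image: %d x %d (%s region)%s, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$region,
              if (x$chromatic) ", chromatic" else "",
              min(x$values), max(x$values)))
  invisible(x)
}

# clip to [0,1], recording how much got clipped (dims preserved)
clip01 <- function(values) {
  frac <- mean(values < 0 | values > 1)
  values[values < 0] <- 0
  values[values > 1] <- 1
  list(values = values, clip_fraction = frac)
}
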