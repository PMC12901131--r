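# Central cutout diameters (pixels) registered per spatial-frequency level.
# Small central disks are removed to avoid aliasing where local spatial
# frequency diverges as eccentricity -> 0.
spiral_cutout_table <- c("6" = 4, "11" = 8, "20" = 14, "37" = 26,
                         "69" = 48, "128" = 86)

# Named spiral types and their log-polar mixing angles (radians).
# alpha = pi/2 gives a pinwheel (pure angular modulation), alpha = 0 an
# annulus (pure radial modulation); intermediates are forward/reverse
# spirals. The letter -> angle assignment is a package convention and is
# configurable via the alpha argument of make_spiral_grating().
spiral_type_angles <- c(A = pi / 2, B = pi / 4, C = 0, D = -pi / 4,
                        E = 3 * pi / 8, F = pi / 8, G = -pi / 8, H = -3 * pi / 8)

# Integer-continuity parameterization: B rounded to an integer angular
# frequency (no seam at theta = 0), then the radial coefficient A is
# re-lengthened so sqrt(A^2 + B^2) = L and the local spatial frequency law
# L / (2 pi E) holds exactly.
spiral_coefficients <- function(L, alpha) {
  if (L <= 0) stop("spatial-frequency level L must be positive")
  B <- round(L * sin(alpha))
  if (abs(B) > L)
    stop("alpha rounds the angular frequency beyond L; cannot renormalize")
  A <- sign(cos(alpha)) * sqrt(L^2 - B^2)
  list(A = A, B = B)
}

# Phase map psi(x, y) = A * ln(E) + B * theta over the central square,
# in visual-field coordinates. Exposed for numerical verification of the
# local spatial-frequency law |grad psi| / (2 pi) = L / (2 pi E).
#' Log-polar spiral phase map
#'
#' Returns the phase map (radians) of a spiral grating over the central
#' square, before the cosine is applied. Useful for verifying the local
#' spatial-frequency law numerically.
#'
#' @param geometry A `display_geometry`.
#' @param L Spatial-frequency level (> 0).
#' @param alpha Mixing angle in radians.
#' @return A list with `psi` (phase matrix), `ecc` (eccentricity in
#'   degrees), and the integerized coefficients `A`, `B`.
#' @export
spiral_phase_map <- function(geometry = display_geometry(), L, alpha) {
  co <- spiral_coefficients(L, alpha)
  side <- geometry$square_px
  half_deg <- geometry$field_h / 2
  # pixel centers in degrees, origin at canvas center
  coord <- (seq_len(side) - (side + 1) / 2) / geometry$ppd
  x <- matrix(rep(coord, each = side), side, side)   # column -> horizontal
  y <- matrix(rep(coord, times = side), side, side)  # row -> vertical
  ecc <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  psi <- co$A * log(pmax(ecc, .Machine$double.eps)) + co$B * theta
  list(psi = psi, ecc = ecc, A = co$A, B = co$B, half_deg = half_deg)
}

#' Log-polar spiral grating
#'
#' Renders `0.5 + 0.5 * cos(A * ln(E) + B * theta + phase)` over the
#' central square, where `E` is eccentricity in degrees and `theta` polar
#' angle. The coefficients are `A = L * cos(alpha)` and
#' `B = round(L * sin(alpha))` (integer angular frequency, so the pattern
#' is continuous across theta = 0), renormalized so that
#' `sqrt(A^2 + B^2) = L`; the local spatial frequency at eccentricity `E`
#' is then exactly `L / (2 * pi * E)` cycles per degree regardless of
#' `alpha`. A central disk of diameter `cutout_px` and everything outside
#' the central square are set to background gray.
#'
#' @param geometry A `display_geometry`.
#' @param L Spatial-frequency level; the study levels are
#'   6, 11, 20, 37, 69 and 128.
#' @param alpha Mixing angle in radians, or a spiral type letter
#'   `"A"`..`"H"` (pinwheel, forward spiral, annulus, reverse spiral, and
#'   four intermediates).
#' @param phase Grating phase in radians.
#' @param cutout_px Diameter of the central cutout in pixels; defaults to
#'   the registered value for the study levels.
#' @return A `luminance_image` at full contrast.
#' @export
make_spiral_grating <- function(geometry = display_geometry(), L, alpha,
                                phase = 0, cutout_px = NULL) {
  if (is.character(alpha)) {
    if (!alpha %in% names(spiral_type_angles)) stop("unknown spiral type letter")
    alpha <- spiral_type_angles[[alpha]]
  }
  if (is.null(cutout_px)) {
    key <- as.character(L)
    if (!key %in% names(spiral_cutout_table))
      stop("no registered cutout for this L; supply cutout_px")
    cutout_px <- spiral_cutout_table[[key]]
  }
  pm <- spiral_phase_map(geometry, L, alpha)
  vals <- 0.5 + 0.5 * cos(pm$psi + phase)
  cut_deg <- (cutout_px / 2) / geometry$ppd
  vals[pm$ecc < cut_deg] <- 0.5
  luminance_image(vals, geometry)
}
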