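# Registered constants of the stimulus family
contrast_levels <- c(1.0, 0.5, 0.1, 0.06, 0.04)     # 100% level = unmodulated scenes
phase_coherence_levels <- c(0.75, 0.50, 0.25, 0.0)
spiral_sf_levels <- c(6, 11, 20, 37, 69, 128)
word_positions_deg <- c(-6, -3, 0, 3, 6)
grating_phases <- c(0, pi / 2, pi, 3 * pi / 2)
hue00_contrast_scale <- 0.5                          # reduced-contrast chromatic base

#' Subclass registry of the 284-image synthetic stimulus set
#'
#' The set contains 284 images in 71 subclasses of 4 images each, grouped
#' into 8 classes: Noise (subclasses 1-3 and 55), Natural scenes (4, 8),
#' Manipulated scenes (5-7), Contrast modulation (9-12), Phase-coherence
#' modulation (13-16), Single words (17-26), Spiral gratings (27-54) and
#' Chromatic noise (56-71).
#'
#' @return A data frame with one row per subclass: `subclass_index`,
#'   `subclass_name`, `class`, `n_images`, `first_index`, `last_index`.
#' @export
subclass_registry <- function() {
  nm <- character(71); cl <- character(71)
  nm[1] <- "White noise";              cl[1] <- "Noise"
  nm[2] <- "White noise (large block)"; cl[2] <- "Noise"
  nm[3] <- "Pink noise";               cl[3] <- "Noise"
  nm[4] <- "Natural scenes";           cl[4] <- "Natural scenes"
  nm[5] <- "Upside-down scenes";       cl[5] <- "Manipulated scenes"
  nm[6] <- "Mooney scenes";            cl[6] <- "Manipulated scenes"
  nm[7] <- "Line-drawing scenes";      cl[7] <- "Manipulated scenes"
  nm[8] <- "Natural scenes (second set)"; cl[8] <- "Natural scenes"
  nm[9:12] <- paste0("Contrast ", c(50, 10, 6, 4), "%")
  cl[9:12] <- "Contrast modulation"
  nm[13:16] <- paste0("Phase ", c(75, 50, 25, 0), "%")
  cl[13:16] <- "Phase-coherence modulation"
  nm[17:21] <- paste0("Word4 Pos", 1:5); cl[17:21] <- "Single words"
  nm[22:26] <- paste0("Word6 Pos", 1:5); cl[22:26] <- "Single words"
  k <- 27
  for (type in c("A", "B", "C", "D")) for (sf in 1:6) {
    nm[k] <- sprintf("Spiral%s SF%d", type, sf); cl[k] <- "Spiral gratings"; k <- k + 1
  }
  for (type in c("E", "F", "G", "H")) {
    nm[k] <- sprintf("Spiral%s SF4", type); cl[k] <- "Spiral gratings"; k <- k + 1
  }
  nm[55] <- "Hue00"; cl[55] <- "Noise"
  nm[56:71] <- sprintf("Hue%02d", 1:16); cl[56:71] <- "Chromatic noise"
  n_images <- rep(4L, 71)
  last <- cumsum(n_images)
  data.frame(subclass_index = 1:71, subclass_name = nm, class = cl,
             n_images = n_images, first_index = last - n_images + 1L,
             last_index = last, stringsAsFactors = FALSE)
}

#' Build the complete 284-image synthetic stimulus set
#'
#' Deterministically renders all 71 subclasses on the given display
#' geometry. Stochastic subclasses (noise and phase randomization) derive
#' their draws from `seed`; scene photographs are either user-supplied or
#' produced by the procedural fixture generator under `scene_seed`, which
#' is independent of `seed` so that regenerating with a different `seed`
#' changes only the stochastic subclasses.
#'
#' @param seed Integer seed for all stochastic subclasses.
#' @param scene_sources Optional list of exactly 8 raster images (matrices
#'   or RGB arrays in [0, 1]) standing in for the scene photographs;
#'   sources 1-4 feed the first scene set, 5-8 the second.
#' @param geometry A `display_geometry`.
#' @param scene_seed Seed for the procedural scene fixtures when
#'   `scene_sources` is absent.
#' @param gamut_radius Maximum chroma magnitude for the chromatic class.
#' @return A `stimulus_set`: list with `images` (284 `luminance_image`s),
#'   `manifest` (284-row data frame: index, class, subclass_index,
#'   subclass_name, generator_params JSON, seed), `registry` (the
#'   subclass table) and `seed`.
#' @export
build_full_set <- function(seed = 1L, scene_sources = NULL,
                           geometry = display_geometry(),
                           scene_seed = 2024L, gamut_radius = 0.35) {
  reg <- subclass_registry()
  if (is.null(scene_sources)) {
    scene_sources <- make_naturalistic_fixtures(8, seed = scene_seed,
                                                side = geometry$square_px)
  }
  if (length(scene_sources) != 8L)
    stop("scene_sources must contain exactly 8 images")

  images <- vector("list", 284L)
  params <- vector("list", 284L)
  put <- function(sc, i, img, par) {
    idx <- reg$first_index[sc] + i - 1L
    images[[idx]] <<- img
    params[[idx]] <<- par
  }

  # Noise subclasses 1-3
  for (i in 1:4) {
    put(1L, i, make_white_noise(geometry, 1L, child_seed(seed, i)),
        list(block_px = 1))
    put(2L, i, make_white_noise(geometry, 42L, child_seed(seed, 10 + i)),
        list(block_px = 42))
    put(3L, i, make_pink_noise(geometry, child_seed(seed, 20 + i)),
        list(clip_sd = 3.5))
  }

  # Scenes and manipulations (subclasses 4-8)
  scenes1 <- lapply(scene_sources[1:4], prep_scene, geometry = geometry)
  scenes2 <- lapply(scene_sources[5:8], prep_scene, geometry = geometry)
  for (i in 1:4) {
    put(4L, i, scenes1[[i]], list(source = i))
    put(5L, i, upside_down(scenes1[[i]]), list(source = i))
    put(6L, i, mooney(scenes1[[i]]), list(source = i))
    put(7L, i, line_drawing_substitute(scenes1[[i]]),
        list(source = i, substitute = "sobel-edge line drawing"))
    put(8L, i, scenes2[[i]], list(source = 4 + i))
  }

  # Contrast modulation of the second scene set (subclasses 9-12)
  for (s in 1:4) for (i in 1:4) {
    cc <- contrast_levels[s + 1]
    put(8L + s, i, contrast_modulate(scenes2[[i]], cc),
        list(source = 4 + i, contrast = cc))
  }

  # Phase-coherence modulation of the Contrast-50% images (subclasses 13-16)
  c50 <- lapply(scenes2, contrast_modulate, c = 0.5)
  for (s in 1:4) for (i in 1:4) {
    k <- phase_coherence_levels[s]
    put(12L + s, i,
        phase_coherence_blend(c50[[i]], k, child_seed(seed, 100 + 10 * s + i)),
        list(source = 4 + i, coherence = k))
  }

  # Single words (subclasses 17-26)
  for (len_i in 1:2) {
    len <- c(4L, 6L)[len_i]
    words <- default_word_list(len)
    for (pos in 1:5) for (i in 1:4) {
      w <- words[(pos - 1L) * 4L + i]
      put(16L + (len_i - 1L) * 5L + pos, i,
          render_word(w, len, word_positions_deg[pos], geometry),
          list(word = w, position_deg = word_positions_deg[pos]))
    }
  }

  # Spiral gratings (subclasses 27-54)
  sc <- 27L
  spiral_plan <- c(lapply(c("A", "B", "C", "D"), function(t) lapply(1:6, function(s) c(t, s))),
                  lapply(c("E", "F", "G", "H"), function(t) list(c(t, 4))))
  for (per_type in spiral_plan) for (ts in per_type) {
    type <- ts[1]; sf <- as.integer(ts[2])
    L <- spiral_sf_levels[sf]
    for (i in 1:4) {
      put(sc, i, make_spiral_grating(geometry, L, type, grating_phases[i]),
          list(type = type, L = L, phase = grating_phases[i],
               alpha = unname(spiral_type_angles[type])))
    }
    sc <- sc + 1L
  }

  # Hue00: reduced-contrast versions of the pink-noise patterns (subclass 55)
  hue00 <- lapply(1:4, function(i)
    make_pink_noise(geometry, child_seed(seed, 20 + i),
                    contrast_scale = hue00_contrast_scale))
  for (i in 1:4) put(55L, i, hue00[[i]],
                     list(contrast_scale = hue00_contrast_scale))

  # Chromatic noise (subclasses 56-71): 16 hues x 4 base patterns
  for (h in 1:16) for (i in 1:4) {
    put(55L + h, i,
        make_chromatic_noise(geometry, h, hue00[[i]], gamut_radius),
        list(hue_index = h, base_pattern = i, gamut_radius = gamut_radius))
  }

  manifest <- data.frame(
    index = 1:284,
    class = rep(reg$class, reg$n_images),
    subclass_index = rep(reg$subclass_index, reg$n_images),
    subclass_name = rep(reg$subclass_name, reg$n_images),
    generator_params = vapply(params, function(p)
      as.character(jsonlite::toJSON(p, auto_unbox = TRUE)), character(1)),
    seed = seed, stringsAsFactors = FALSE)

  structure(list(images = images, manifest = manifest, registry = reg,
                 seed = seed, geometry = geometry),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("stimulus set: %d images, %d subclasses, %d classes (seed %s)\n",
              length(x$images), nrow(x$registry),
              length(unique(x$registry$class)), format(x$seed)))
  print(table(x$manifest$class))
  invisible(x)
}

# generic opponent-plane export LUT: luminance rides a warm-white primary
# whose maximum RGB is (252, 220, 216); chroma channels tilt R-G and B-Y
lut_export_rgb <- function(img) {
  l <- as_canvas(img)
  white <- c(252, 220, 216) / 255
  if (!img$chromatic) {
    arr <- array(0, c(dim(l), 3L))
    for (ch in 1:3) arr[, , ch] <- l * white[ch]
    return(arr)
  }
  g <- img$geometry
  pad <- function(m) {
    if (img$region == "full") return(m)
    out <- matrix(0, g$canvas_h, g$canvas_w)
    x0 <- (g$canvas_w - g$square_px) %/% 2L
    out[, (x0 + 1L):(x0 + g$square_px)] <- m
    out
  }
  c1 <- pad(img$chroma[[1]]); c2 <- pad(img$chroma[[2]])
  arr <- array(0, c(dim(l), 3L))
  arr[, , 1] <- l + 0.5 * c1 + 0.25 * c2
  arr[, , 2] <- l - 0.5 * c1 + 0.25 * c2
  arr[, , 3] <- l - 0.5 * c2
  arr[arr < 0] <- 0; arr[arr > 1] <- 1
  for (ch in 1:3) arr[, , ch] <- arr[, , ch] * white[ch]
  arr
}

#' Export a stimulus set as PNG files plus a manifest
#'
#' Writes one PNG per image, named `{index:03d}_{class}_{subclass}.png`
#' (achromatic images as grayscale through the export lookup table's
#' luminance ramp, chromatic images as RGB), and `manifest.csv` with the
#' generation parameters.
#'
#' @param set A `stimulus_set`.
#' @param dir Output directory (created if missing).
#' @param indices Which image indices to export (default all).
#' @return Invisibly, the vector of file paths written.
#' @export
export_stimulus_set <- function(set, dir, indices = seq_along(set$images)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slug <- function(s) gsub("[^A-Za-z0-9]+", "-", s)
  paths <- character(length(indices))
  for (j in seq_along(indices)) {
    i <- indices[j]
    img <- set$images[[i]]
    fn <- sprintf("%03d_%s_%s.png", i, slug(set$manifest$class[i]),
                  slug(set$manifest$subclass_name[i]))
    path <- file.path(dir, fn)
    png::writePNG(lut_export_rgb(img), path)
    paths[j] <- path
  }
  utils::write.csv(set$manifest[indices, , drop = FALSE],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(paths)
}
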