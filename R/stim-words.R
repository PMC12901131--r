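# Built-in 5 x 7 monospaced uppercase bitmap font. Glyphs are rendered as
# black ink on gray; every glyph has ink in both its leftmost and rightmost
# column in at least one row, so a rendered word's ink bounding box is
# centered on the word's nominal center. A bitmap font keeps the renderer
# deterministic and free of system font dependencies; glyphs are scaled to
# the stated x-heights (tolerance +/- 5%).
bitmap_font_5x7 <- local({
  g <- list(
    A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    B = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
    C = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
    D = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
    E = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
    F = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
    G = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".####"),
    H = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    I = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
    J = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
    K = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
    L = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
    M = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
    N = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
    O = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    P = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
    Q = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
    R = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
    S = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
    T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    U = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    V = c("#...#", "#...#", "#...#", "#...#", ".#.#.", ".#.#.", "..#.."),
    W = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
    X = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
    Y = c("#...#", ".#.#.", "..#..", "..#..", "..#..", "..#..", "..#.."),
    Z = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"))
  lapply(g, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#"))
    storage.mode(m) <- "logical"
    m
  })
})

# Default word lists: 20 four-letter and 20 six-letter common nouns.
# Words 4k-3 .. 4k are assigned to position k (k = 1..5, i.e. -6, -3, 0,
# 3, 6 degrees) when the full stimulus set is built.
#' @rdname render_word
#' @export
default_word_list <- function(length_class) {
  w4 <- c("LAKE", "FISH", "BIRD", "SAND", "WIND", "ROCK", "TREE", "MOON",
          "STAR", "RAIN", "SNOW", "FIRE", "ROAD", "DOOR", "HAND", "BOOK",
          "SONG", "GOLD", "BLUE", "KING")
  w6 <- c("GARDEN", "WINTER", "SILVER", "FOREST", "BRIDGE", "CASTLE",
          "PLANET", "FLOWER", "STREAM", "MARKET", "WINDOW", "BOTTLE",
          "CIRCLE", "LETTER", "MOMENT", "SUMMER", "VALLEY", "SHADOW",
          "ANIMAL", "ORANGE")
  switch(as.character(length_class), "4" = w4, "6" = w6,
         stop("length_class must be 4 or 6"))
}

# nearest-neighbor upscale of a logical glyph to h_px x w_px
scale_glyph <- function(glyph, h_px, w_px) {
  ri <- pmin(nrow(glyph), pmax(1L, ceiling(seq_len(h_px) / h_px * nrow(glyph))))
  ci <- pmin(ncol(glyph), pmax(1L, ceiling(seq_len(w_px) / w_px * ncol(glyph))))
  glyph[ri, ci, drop = FALSE]
}

#' Render a single-word stimulus
#'
#' Draws one uppercase word in a built-in monospaced bitmap font, black
#' ink (0) on a gray background (0.5), centered vertically and placed at
#' `position_deg` along the horizontal meridian. Four-letter words use an
#' x-height of 0.4 deg with 0.43 deg center-to-center letter spacing;
#' six-letter words use 0.27 deg and 0.28 deg respectively.
#'
#' @param word Uppercase word (A-Z only); its number of letters must match
#'   `length_class`.
#' @param length_class 4 or 6.
#' @param position_deg Horizontal position of the word center in degrees:
#'   one of -6, -3, 0, 3, 6 in the standard set.
#' @param geometry A `display_geometry`.
#' @return A `luminance_image` (full-canvas region if ink extends beyond
#'   the central square, as it does at +/- 6 deg).
#' @export
render_word <- function(word, length_class = nchar(word), position_deg = 0,
                        geometry = display_geometry()) {
  word <- toupper(word)
  letters_vec <- strsplit(word, "")[[1]]
  if (length(letters_vec) != length_class)
    stop(sprintf("word '%s' does not have %d letters", word, length_class))
  if (!all(letters_vec %in% names(bitmap_font_5x7)))
    stop("word must consist of letters A-Z")
  spec <- switch(as.character(length_class),
                 "4" = list(xheight_deg = 0.4, spacing_deg = 0.43),
                 "6" = list(xheight_deg = 0.27, spacing_deg = 0.28),
                 stop("length_class must be 4 or 6"))
  h_px <- round(deg_to_px(geometry, spec$xheight_deg))
  w_px <- round(h_px * 5 / 7)
  spacing_px <- deg_to_px(geometry, spec$spacing_deg)
  n <- length(letters_vec)
  canvas <- matrix(0.5, geometry$canvas_h, geometry$canvas_w)
  cx <- (geometry$canvas_w + 1) / 2 + deg_to_px(geometry, position_deg)
  cy <- (geometry$canvas_h + 1) / 2
  r0 <- round(cy - h_px / 2)
  for (i in seq_len(n)) {
    lcx <- cx + (i - (n + 1) / 2) * spacing_px
    c0 <- round(lcx - w_px / 2)
    if (c0 < 1L || c0 + w_px - 1L > geometry$canvas_w)
      stop("word extends beyond the canvas")
    gl <- scale_glyph(bitmap_font_5x7[[letters_vec[i]]], h_px, w_px)
    block <- canvas[r0:(r0 + h_px - 1L), c0:(c0 + w_px - 1L)]
    block[gl] <- 0
    canvas[r0:(r0 + h_px - 1L), c0:(c0 + w_px - 1L)] <- block
  }
  # store only the central square when the flanks carry no ink
  x0 <- (geometry$canvas_w - geometry$square_px) %/% 2L
  central_cols <- (x0 + 1L):(x0 + geometry$square_px)
  if (all(canvas[, -central_cols] == 0.5)) {
    luminance_image(canvas[, central_cols, drop = FALSE], geometry)
  } else {
    luminance_image(canvas, geometry, region = "full")
  }
}
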