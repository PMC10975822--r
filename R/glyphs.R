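# Built-in binary glyph masks used as test objects. The digits mimic the
# Group-1 elements of a negative resolution test plate ('4', '5') plus a
# three-bar element ('bars') and a single-pixel point source ('dot').

.glyph_masks <- local({
  parse_mask <- function(rows) {
    do.call(rbind, lapply(strsplit(rows, ""), function(r) as.integer(r == "#")))
  }
  list(
    `5` = parse_mask(c(
      "#####",
      "#....",
      "#....",
      "####.",
      "....#",
      "#...#",
      ".###."
    )),
    `4` = parse_mask(c(
      "...#.",
      "..##.",
      ".#.#.",
      "#..#.",
      "#####",
      "...#.",
      "...#."
    )),
    bars = parse_mask(c(
      "#####",
      ".....",
      "#####",
      ".....",
      "#####"
    )),
    dot = matrix(1L, 1, 1)
  )
})

#' Available glyph identifiers
#' @return character vector of glyph ids accepted by [make_object()].
#' @export
glyph_ids <- function() names(.glyph_masks)

# Nearest-neighbour upscale of a binary mask to target height `h2`
# (width scaled to preserve aspect ratio).
scale_mask <- function(mask, h2) {
  h <- nrow(mask); w <- ncol(mask)
  w2 <- max(1L, as.integer(round(h2 * w / h)))
  ri <- pmin(h, pmax(1L, ceiling(seq_len(h2) * h / h2)))
  ci <- pmin(w, pmax(1L, ceiling(seq_len(w2) * w / w2)))
  mask[ri, ci, drop = FALSE]
}

#' Build a glyph object image on a canvas
#'
#' Rasterizes a built-in binary glyph, scales it to the requested support
#' (largest dimension in pixels) and centers it on a zero canvas. Objects must
#' be small relative to the frame so the shift-invariant (memory-effect)
#' convolution model holds.
#'
#' @param glyph glyph id, see [glyph_ids()].
#' @param canvas integer vector `c(rows, cols)` of the frame.
#' @param support target glyph height in pixels; must be `< min(canvas)/4`.
#' @return an `object_image`: list with `intensities` (matrix) and
#'   `support_extent` (realized bounding-box size in pixels).
#' @export
make_object <- function(glyph, canvas = c(256L, 256L), support = 32L) {
  if (length(canvas) == 1) canvas <- rep(canvas, 2)
  if (!is.character(glyph) || !glyph %in% names(.glyph_masks)) {
    stop("unknown glyph '", glyph, "'; available: ",
         paste(glyph_ids(), collapse = ", "))
  }
  if (support >= min(canvas) / 4) {
    stop("support must be < canvas/4 (memory-effect assumption)")
  }
  mask <- .glyph_masks[[glyph]]
  m <- if (identical(glyph, "dot") && support <= 1) mask else scale_mask(mask, support)
  img <- center_embed(m, as.integer(canvas))
  structure(list(intensities = img, support_extent = max(dim(m)), glyph = glyph),
            class = "object_image")
}

#' @export
print.object_image <- function(x, ...) {
  cat(sprintf("<object_image> glyph '%s', %d x %d canvas, support %d px, %d nonzero px\n",
              x$glyph, nrow(x$intensities), ncol(x$intensities),
              x$support_extent, sum(x$intensities > 0)))
  invisible(x)
}
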