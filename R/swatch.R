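#' Swatch images
#'
#' A swatch is a rectangular crop of the dorsal surface, oriented so that
#' matrix columns run head-to-tail along the longitudinal body axis: moving
#' down within a column is movement along the body, moving across a row is
#' movement transversely (left/right) across the body. Pixels are 8-bit RGB.
#'
#' @param pixels an `H x W x 3` array (or an `H x W` matrix, interpreted as a
#'   grey image with R = G = B) of integer channel values in `[0, 255]`.
#' @param image_id identifier carried through to metric tables.
#' @return an object of class `swatch_image`: a list with elements `pixels`
#'   (H x W x 3 integer array) and `image_id`.
#' @export
swatch_image <- function(pixels, image_id = "swatch") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array or an H x W matrix")
  }
  if (dim(pixels)[1] < 2L || dim(pixels)[2] < 2L) {
    stop("swatch must be at least 2 x 2 pixels")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  structure(list(pixels = round(pixels), image_id = as.character(image_id)),
            class = "swatch_image")
}

#' @export
print.swatch_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<swatch_image '%s': %d x %d px (rows transverse, cols longitudinal axis down)>\n",
              x$image_id, d[1], d[2]))
  invisible(x)
}

#' @export
dim.swatch_image <- function(x) dim(x$pixels)

#' White-balance a swatch against a grey standard
#'
#' Each channel is scaled by `255 / standard`, so a pixel of the imaged white
#' standard maps to (255, 255, 255). Values are rounded half-up and clipped
#' to `[0, 255]`.
#'
#' @param image a [swatch_image].
#' @param standard_rgb length-3 numeric: the mean (R, G, B) of the white
#'   standard region in the same photograph. All entries must be positive.
#' @return a white-balanced [swatch_image].
#' @export
white_balance <- function(image, standard_rgb) {
  stopifnot(inherits(image, "swatch_image"))
  standard_rgb <- as.numeric(standard_rgb)
  if (length(standard_rgb) != 3L || anyNA(standard_rgb)) {
    stop("`standard_rgb` must be three finite channel values")
  }
  if (any(standard_rgb <= 0)) {
    stop("white standard has a zero or negative channel; cannot white-balance")
  }
  px <- image$pixels
  for (ch in 1:3) {
    # multiply before dividing so exact halves stay exact, then round
    # half-up (base round() is half-to-even)
    px[, , ch] <- pmin(255, pmax(0, floor(px[, , ch] * 255 / standard_rgb[ch] + 0.5)))
  }
  swatch_image(px, image$image_id)
}

#' Mean brightness of a swatch
#'
#' Per-pixel brightness is `(R/255 + G/255 + B/255)/3`; the swatch value is
#' the mean over all pixels. Dimensionless, in `[0, 1]`, and invariant to any
#' spatial rearrangement of pixels.
#'
#' @param image a [swatch_image].
#' @return a single numeric brightness in `[0, 1]`.
#' @export
mean_brightness <- function(image) {
  stopifnot(inherits(image, "swatch_image"))
  mean(image$pixels) / 255
}

#' Brightness of a single RGB triple
#' @param rgb length-3 numeric (R, G, B) in `[0, 255]`.
#' @return numeric in `[0, 1]`.
#' @export
rgb_brightness <- function(rgb) {
  stopifnot(length(rgb) == 3L)
  sum(rgb / 255) / 3
}

#' Read / write swatches as PNG
#'
#' Swatches are stored as ordinary 8-bit RGB PNG files. Grey images written
#' by the renderer are expanded to three identical channels on read.
#'
#' @param path file path.
#' @param image_id identifier; defaults to the file name without extension.
#' @return [read_swatch_png()] returns a [swatch_image];
#'   [write_swatch_png()] invisibly returns `path`.
#' @export
read_swatch_png <- function(path, image_id = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  arr <- arr[, , 1:3, drop = FALSE] # drop alpha if present
  id <- image_id %||% sub("\\.png$", "", basename(path), ignore.case = TRUE)
  swatch_image(round(arr * 255), id)
}

#' @rdname read_swatch_png
#' @param image a [swatch_image] to write.
#' @export
write_swatch_png <- function(image, path) {
  stopifnot(inherits(image, "swatch_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
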