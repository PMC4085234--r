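#' Gel image container
#'
#' A `gel_image` holds a single-channel 2-DE gel or immunoblot image as a
#' floating-point matrix in arbitrary densitometric units, together with the
#' intensity at which the acquiring camera clips (if known).
#'
#' Coordinate convention: pixel coordinates are 0-based with `x` the column
#' index and `y` the row index, so pixel `(x, y)` is `pixels[y + 1, x + 1]`.
#' Pixel centers sit at integer coordinates.
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x).
#' @param saturation_level Optional intensity at which the camera clips;
#'   no pixel may exceed it.
#' @return An object of class `gel_image` with fields `pixels`, `height`,
#'   `width` and `saturation_level`.
#' @examples
#' img <- gel_image(matrix(runif(100), 10, 10))
#' dim(img$pixels)
#' @export
gel_image <- function(pixels, saturation_level = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("all pixel values must be finite", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (!is.null(saturation_level)) {
    stopifnot(is.numeric(saturation_level), length(saturation_level) == 1L)
    if (any(pixels > saturation_level))
      stop("pixels exceed the stated saturation_level", call. = FALSE)
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         saturation_level = saturation_level),
    class = "gel_image"
  )
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image> %d x %d pixels, range [%.4g, %.4g]%s\n",
              x$width, x$height, min(x$pixels), max(x$pixels),
              if (is.null(x$saturation_level)) ""
              else sprintf(", saturation %.4g", x$saturation_level)))
  invisible(x)
}

as_gel_image <- function(x) {
  if (inherits(x, "gel_image")) x else gel_image(as.matrix(x))
}

# Intensity at 0-based (x, y); vectorized over equal-length x and y.
pixel_at <- function(image, x, y) {
  image$pixels[cbind(y + 1L, x + 1L)]
}
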