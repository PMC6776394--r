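#' Single-channel fluorescence images
#'
#' A `fluor_image` is a numeric matrix of intensity counts (rows = image
#' rows, 1-based pixel-centre coordinates) carrying the channel role
#' (`"donor"`, `"acceptor"`, `"fret"`, `"brightfield"`, `"green"`, `"red"`,
#' or `"plate"`) and, when known, the pixel size in mm as attributes.
#'
#' @param pixels numeric matrix of counts.
#' @param channel channel role string.
#' @param mm_per_px optional pixel size, mm per pixel.
#' @return A `fluor_image` object.
#' @export
fluor_image <- function(pixels, channel = "unknown", mm_per_px = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  structure(pixels, channel = channel, mm_per_px = mm_per_px,
            class = c("fluor_image", "matrix", "array"))
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image> %d x %d px, channel = %s, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "channel"), min(x), max(x)))
  if (!is.na(attr(x, "mm_per_px"))) {
    cat(sprintf("  pixel size: %g mm/px\n", attr(x, "mm_per_px")))
  }
  invisible(x)
}

#' Write a fluorescence image as 16-bit grayscale TIFF
#'
#' Counts are clipped to `[0, 2^16 - 1]` and quantized to the 16-bit grid;
#' this is the only place quantization happens for noiseless renders.
#'
#' @param img `fluor_image` or numeric matrix of counts.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fluor_tiff <- function(img, path) {
  x <- round(pmin(pmax(unclass(img), 0), 65535)) / 65535
  tiff::writeTIFF(x, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 16-bit grayscale TIFF as a fluorescence image
#'
#' @param path TIFF file path.
#' @inheritParams fluor_image
#' @return A `fluor_image` with integer counts in `[0, 65535]`.
#' @export
read_fluor_tiff <- function(path, channel = "unknown", mm_per_px = NA_real_) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  fluor_image(round(x * 65535), channel = channel, mm_per_px = mm_per_px)
}

#' Write a ground-truth manifest as JSON
#'
#' @param manifest manifest list as produced by the generators.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a ground-truth manifest written by [write_manifest()]
#'
#' @param path JSON path.
#' @return The manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
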