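#' Single-channel microscopy image
#'
#' A `channel_image` wraps an integer pixel matrix together with its bit
#' depth, channel tag and pixel size. The collagen channel corresponds to the
#' second harmonic generation (SHG) signal and the elastin channel to
#' two-photon excited fluorescence (TPEF). Pixels are stored row-major with
#' the origin at the top-left.
#'
#' @param pixels Integer matrix of nonnegative pixel values.
#' @param channel One of `"collagen"` or `"elastin"`.
#' @param bit_depth Either 8 or 16; all pixel values must be `< 2^bit_depth`.
#' @param pixel_size_um Physical pixel pitch in micrometres (metadata only).
#'   The default corresponds to a 210 um field of view sampled at 512 px.
#'
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = c("collagen", "elastin"),
                          bit_depth = 8L, pixel_size_um = 210 / 512) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    abort("`pixels` must be a nonempty matrix.",
          class = "fibrotype_parameter_error")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    abort("`bit_depth` must be 8 or 16.", class = "fibrotype_parameter_error")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels >= 2^bit_depth)) {
    abort(sprintf("pixel values must lie in [0, %d].", 2^bit_depth - 1),
          class = "fibrotype_parameter_error")
  }
  check_number(pixel_size_um, "pixel_size_um", lower = 1e-9)
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         channel = channel, pixel_size_um = pixel_size_um),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, %d-bit, %.3f um/px\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$pixel_size_um))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

max_level <- function(img) 2L^img$bit_depth - 1L

#' Pair of collagen and elastin images for one imaged region
#'
#' @param collagen,elastin `channel_image` objects with matching dimensions.
#' @param region_id Identifier string for the region.
#' @return An object of class `region_record`.
#' @export
region_record <- function(collagen, elastin, region_id = "region") {
  stopifnot(inherits(collagen, "channel_image"),
            inherits(elastin, "channel_image"))
  if (!identical(dim(collagen$pixels), dim(elastin$pixels))) {
    abort("collagen and elastin images must have identical dimensions.",
          class = "fibrotype_parameter_error")
  }
  if (collagen$channel != "collagen" || elastin$channel != "elastin") {
    abort("channel tags must be collagen / elastin respectively.",
          class = "fibrotype_parameter_error")
  }
  structure(list(collagen = collagen, elastin = elastin,
                 region_id = as.character(region_id)),
            class = "region_record")
}

#' Read a single-channel image from TIFF or PNG
#'
#' Pixel values are loaded losslessly as integers; the bit depth is inferred
#' from the file. Multi-channel (e.g. RGB) files are rejected.
#'
#' @param path Path to a single-channel TIFF or PNG file.
#' @param channel Channel tag to attach, `"collagen"` or `"elastin"`.
#' @param pixel_size_um Pixel pitch metadata to attach.
#' @return A [channel_image()].
#' @export
read_channel_image <- function(path, channel = c("collagen", "elastin"),
                               pixel_size_um = 210 / 512) {
  channel <- match.arg(channel)
  if (!file.exists(path)) {
    abort(sprintf("image file not found: %s", path),
          class = "fibrotype_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = {
      x <- png::readPNG(path)
      bits <- if (max(x) <= 1 && is.double(x)) {
        # png returns [0,1]; recover integer scale from encoded depth
        attr(x, "bit.depth") %||% 8L
      } else 8L
      x * (2^bits - 1)
    },
    abort(sprintf("unsupported image format '%s' for file %s", ext, path),
          class = "fibrotype_format_error")
  )
  if (length(dim(raw)) != 2L) {
    abort(sprintf("expected a single-channel image, got %d channels: %s",
                  dim(raw)[3], path),
          class = "fibrotype_format_error")
  }
  maxv <- max(raw)
  bit_depth <- if (ext %in% c("tif", "tiff")) {
    if (attr(raw, "bits.per.sample") %||% (if (maxv > 255) 16L else 8L) > 8) 16L else 8L
  } else {
    if (maxv > 255) 16L else 8L
  }
  channel_image(round(raw), channel = channel, bit_depth = bit_depth,
                pixel_size_um = pixel_size_um)
}

#' Write a channel image to TIFF or PNG
#'
#' @param img A [channel_image()].
#' @param path Destination path; format chosen by extension (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_channel_image <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  ext <- tolower(tools::file_ext(path))
  scaled <- img$pixels / max_level(img)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = img$bit_depth,
                    compression = "none")
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else {
    abort(sprintf("unsupported image format '%s'", ext),
          class = "fibrotype_format_error")
  }
  invisible(path)
}

#' Median-filter denoising
#'
#' Applies a square median filter (default 3x3, edge-replicated borders), the
#' conventional shot-noise remover for photon-counting microscopy. The window
#' size is configurable and `window = 1` (or `"none"`) disables filtering.
#'
#' @param img A [channel_image()].
#' @param window Odd window size in pixels, or `"none"`.
#' @return A [channel_image()] of identical dimensions and bit depth.
#' @export
denoise <- function(img, window = 3L) {
  stopifnot(inherits(img, "channel_image"))
  if (identical(window, "none")) return(img)
  window <- check_count(window, "window", lower = 1L)
  if (window %% 2L == 0L) {
    abort("`window` must be odd.", class = "fibrotype_parameter_error")
  }
  if (window == 1L) return(img)
  out <- img
  out$pixels <- cpp_median_filter(img$pixels, window)
  out
}
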