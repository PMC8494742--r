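# Raster I/O. 16-bit scalar rasters are written as lossless 16-bit TIFF,
# binary masks as 8-bit PNG (0 = FALSE, 255 = TRUE), color-coded maps as
# 24-bit PNG, and RIRT maps as 32-bit float TIFF. Scalar maps carry a JSON
# sidecar recording units and scalar range so physical values survive the
# 16-bit quantization.

#' Write / read a 16-bit en-face angiogram
#'
#' @param img an [enface_angiogram].
#' @param path output file (TIFF).
#' @export
write_angiogram <- function(img, path) {
  tiff::writeTIFF(unclass(img) / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_angiogram
#' @param layer,pixel_pitch_um,slab metadata to attach on read.
#' @export
read_angiogram <- function(path, layer = "DCP", pixel_pitch_um = 10,
                           slab = "") {
  m <- tiff::readTIFF(path)
  enface_angiogram(round(m * 65535), layer = layer,
                   pixel_pitch_um = pixel_pitch_um, slab = slab)
}

#' Save / load a binary region mask
#'
#' Masks are 8-bit single-channel PNG files with 0 for FALSE and 255 for
#' TRUE; on load any nonzero pixel reads as TRUE. The round trip is lossless.
#'
#' @param mask a [region_mask] (or logical matrix).
#' @param path PNG path.
#' @export
save_mask <- function(mask, path) {
  png::writePNG(as_binary_matrix(mask) * 1, path)
  invisible(path)
}

#' @rdname save_mask
#' @param name region name for the loaded mask.
#' @param pixel_pitch_um pixel pitch metadata.
#' @param expect_dim optional `c(rows, cols)`; dimensions are checked when
#'   given and a mismatch is an error.
#' @export
load_mask <- function(path, name, pixel_pitch_um = 10, expect_dim = NULL) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (!is.null(expect_dim) && !identical(dim(m), as.integer(expect_dim)))
    stop(sprintf("mask %s is %d x %d, expected %d x %d", path,
                 nrow(m), ncol(m), expect_dim[1], expect_dim[2]))
  region_mask(m > 0, name = name, pixel_pitch_um = pixel_pitch_um)
}

#' Write / read a scalar map (16-bit TIFF + JSON sidecar)
#'
#' Values are quantized linearly over the map's scalar range into 16 bits;
#' the sidecar (`<path>.json`) records units, range and pixel pitch so the
#' physical scale is recovered on read. `NA` pixels are stored as 0 and a
#' validity channel is not kept; maps with NAs should be saved after
#' replacing them explicitly.
#'
#' @param map a [scalar_map].
#' @param path TIFF path; the sidecar is written next to it.
#' @export
write_scalar_map <- function(map, path) {
  rng <- attr(map, "scalar_range")
  v <- pmin(pmax(unclass(map), rng[1]), rng[2])
  v[is.na(v)] <- rng[1]
  q <- (v - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  tiff::writeTIFF(q, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(units = attr(map, "units"), scalar_range = rng,
         pixel_pitch_um = attr(map, "pixel_pitch_um")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  q <- tiff::readTIFF(path)
  rng <- meta$scalar_range
  scalar_map(q * (rng[2] - rng[1]) + rng[1], units = meta$units,
             pixel_pitch_um = meta$pixel_pitch_um, range = rng)
}

#' Write a 24-bit color map as PNG
#'
#' @param rgb `rows x cols x 3` array of 8-bit channel values (0-255).
#' @param path PNG path.
#' @export
write_color_map <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' @rdname write_color_map
#' @return `read_color_map`: a `rows x cols x 3` array of integers 0-255.
#' @export
read_color_map <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 3) stop("not a color image: ", path)
  round(a[, , 1:3] * 255)
}

#' Write / read a floating-point map (e.g. an RIRT map) as 32-bit float TIFF
#'
#' Values are divided by a positive scale factor (stored in a JSON sidecar)
#' so they fit the TIFF's unit range. NA pixels are stored as 0 and flagged
#' in the sidecar; validity is carried by the accompanying overlap mask,
#' not by the float raster.
#'
#' @param values numeric matrix.
#' @param path TIFF path; a `<path>.json` sidecar records the scale.
#' @export
write_float_map <- function(values, path) {
  v <- as.matrix(values)
  na <- is.na(v)
  scale <- max(1, max(v, na.rm = TRUE))
  q <- pmax(v / scale, 0)
  q[na] <- 0
  tiff::writeTIFF(q, path, bits.per.sample = 32, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(scale = scale, na_zero = any(na)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_float_map
#' @export
read_float_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tiff::readTIFF(path) * meta$scale
}
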