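#' Controlled vocabulary of named retinal regions
#'
#' Region masks in this package carry one of these names: the abnormal (`-A`),
#' normal (`-N`), congestion (`-C`) and foveal-avascular-zone (`-FAZ`) regions
#' of the superficial (SCP) and deep (DCP) capillary plexus, the transitional
#' zone `TZ` (abnormal DCP under normal SCP), the two congestion partition
#' classes, and the diagnostic `residual` class.
#'
#' @export
region_vocabulary <- c(
  "SCP-A", "SCP-N", "SCP-C", "SCP-FAZ",
  "DCP-A", "DCP-N", "DCP-C", "DCP-FAZ",
  "TZ", "DCP-C&TZ", "DCP-C&SCP-A", "residual"
)

#' En-face OCTA angiogram
#'
#' A 16-bit single-channel en-face angiogram of one capillary plexus.
#' Stored as an integer matrix (rows = y, columns = x, origin top-left)
#' with values in `[0, 65535]`, a physical pixel pitch and a record of the
#' depth slab the layer was derived from.
#'
#' @param pixels numeric/integer matrix with values in `[0, 65535]`.
#' @param layer `"SCP"` or `"DCP"`.
#' @param pixel_pitch_um physical pixel pitch in micrometres (device default:
#'   10 um, i.e. 600 px over a 6.0 mm scan).
#' @param slab free-text record of the segmentation slab boundaries.
#' @return an `enface_angiogram` object (matrix with attributes).
#' @export
enface_angiogram <- function(pixels, layer = c("SCP", "DCP"),
                             pixel_pitch_um = 10, slab = "") {
  layer <- match.arg(layer)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) stop("angiogram grid must be square")
  if (pixel_pitch_um <= 0) stop("pixel_pitch_um must be positive")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 65535) stop("pixel values must lie in [0, 65535]")
  structure(round(pixels),
            layer = layer, pixel_pitch_um = pixel_pitch_um, slab = slab,
            class = c("enface_angiogram", "matrix", "array"))
}

#' Scalar map (retinal thickness or vessel density)
#'
#' A decoded per-pixel scalar field on the scan grid: retinal thickness in
#' micrometres or vessel density in percent.
#'
#' @param values numeric matrix.
#' @param units `"um"` (thickness) or `"percent"` (vessel density).
#' @param pixel_pitch_um pixel pitch in micrometres.
#' @param range optional `c(min, max)` scalar range (used when quantizing to
#'   16 bits on disk); defaults to the observed range.
#' @export
scalar_map <- function(values, units = c("um", "percent"),
                       pixel_pitch_um = 10, range = NULL) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (is.null(range)) range <- base::range(values, na.rm = TRUE)
  structure(values, units = units, pixel_pitch_um = pixel_pitch_um,
            scalar_range = range,
            class = c("scalar_map", "matrix", "array"))
}

#' Named binary region mask
#'
#' @param pixels logical (or coercible) matrix; any nonzero value reads TRUE.
#' @param name region name from [region_vocabulary].
#' @param pixel_pitch_um pixel pitch in micrometres.
#' @export
region_mask <- function(pixels, name, pixel_pitch_um = 10) {
  if (!name %in% region_vocabulary)
    stop("unknown region name '", name, "'; see region_vocabulary")
  m <- as.matrix(pixels)
  mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  structure(m, name = name, pixel_pitch_um = pixel_pitch_um,
            class = c("region_mask", "matrix", "array"))
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask '%s'> %d x %d, %d TRUE pixels (%.1f%%)\n",
              attr(x, "name"), nrow(x), ncol(x), sum(x),
              100 * mean(x)))
  invisible(x)
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("<enface_angiogram %s> %d x %d px @ %g um/px, range [%d, %d]\n",
              attr(x, "layer"), nrow(x), ncol(x), attr(x, "pixel_pitch_um"),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map [%s]> %d x %d px, values in [%.3g, %.3g]\n",
              attr(x, "units"), nrow(x), ncol(x),
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

# shared grid check used across modules
check_same_grid <- function(...) {
  dims <- lapply(list(...), dim)
  ref <- dims[[1]]
  ok <- vapply(dims, function(d) identical(d[1:2], ref[1:2]), logical(1))
  if (!all(ok)) stop("inputs do not share one pixel grid")
  invisible(ref)
}

as_binary_matrix <- function(x) {
  m <- as.matrix(x)
  mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  m
}

#' Physical pixel pitch of a scan
#'
#' The en-face scans cover a fovea-centred square field sampled on a square
#' pixel grid; the pitch follows from field width over grid size (6.0 mm over
#' 600 px gives 10 um/px).
#'
#' @param scan_width_mm field width in millimetres (default 6.0).
#' @param grid_px pixels per side (default 600).
#' @return pitch in micrometres per pixel.
#' @export
pixel_pitch_um <- function(scan_width_mm = 6, grid_px = 600) {
  if (scan_width_mm <= 0 || grid_px <= 0) stop("inputs must be positive")
  scan_width_mm * 1000 / grid_px
}

#' Gray-level threshold at a fractional level
#'
#' The brightness criterion for congested capillaries is a gray level greater
#' than 50% of full scale; on a 16-bit image that is `>= 32768`.
#'
#' @param frac fractional level in `(0, 1]` (default 0.5).
#' @param bits bit depth (default 16).
#' @return integer threshold pixel value.
#' @export
gray_level_threshold <- function(frac = 0.5, bits = 16) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  as.integer(ceiling(frac * 2^bits))
}
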