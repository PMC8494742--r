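# Color-map codec. The device exports retinal-thickness and vessel-density
# maps as 24-bit color images; analysis needs the scalar fields back. The
# manufacturer's conversion code is proprietary, so the codec is defined by a
# lookup table (LUT): an ordered list of (scalar, RGB) control points joined
# by piecewise-linear interpolation in RGB. Encoding interpolates; decoding
# finds the nearest color on a densely sampled LUT path and returns its
# scalar, with a validity mask for colors that are off the path.

#' Construct a color lookup table
#'
#' @param values strictly increasing scalar values at the control points.
#' @param colors control-point colors: an `n x 3` matrix of 8-bit RGB values
#'   (0-255).
#' @param units scalar units (`"um"` or `"percent"`).
#' @return a `color_lut` object.
#' @export
color_lut <- function(values, colors, units = c("um", "percent")) {
  units <- match.arg(units)
  colors <- as.matrix(colors)
  if (length(values) < 2) stop("LUT needs at least two control points")
  if (any(diff(values) <= 0))
    stop("LUT scalar values must be strictly increasing")
  if (ncol(colors) != 3 || nrow(colors) != length(values))
    stop("colors must be an n x 3 matrix matching values")
  if (any(colors < 0 | colors > 255)) stop("RGB values must be in [0, 255]")
  seglen <- sqrt(rowSums((colors[-1, , drop = FALSE] -
                          colors[-nrow(colors), , drop = FALSE])^2))
  if (any(seglen == 0)) stop("LUT color path is not injective (repeated color)")
  structure(list(values = as.numeric(values), rgb = colors, units = units,
                 range = range(values)),
            class = "color_lut")
}

#' @export
print.color_lut <- function(x, ...) {
  cat(sprintf("<color_lut> %d control points, range [%g, %g] %s\n",
              length(x$values), x$range[1], x$range[2], x$units))
  invisible(x)
}

#' Default rainbow-style LUTs
#'
#' Blue-to-red five-knot rainbow paths, one per map kind: thickness over
#' 0-500 um and vessel density over 0-100%. The pipeline's results do not
#' depend on the particular LUT — correctness is defined by the
#' encode/decode round-trip contract — but these defaults mimic the look of
#' device exports.
#'
#' @export
default_thickness_lut <- function() {
  color_lut(values = c(0, 125, 250, 375, 500),
            colors = rbind(c(0, 0, 255), c(0, 255, 255), c(0, 255, 0),
                           c(255, 255, 0), c(255, 0, 0)),
            units = "um")
}

#' @rdname default_thickness_lut
#' @export
default_vd_lut <- function() {
  color_lut(values = c(0, 25, 50, 75, 100),
            colors = rbind(c(0, 0, 255), c(0, 255, 255), c(0, 255, 0),
                           c(255, 255, 0), c(255, 0, 0)),
            units = "percent")
}

#' Read / write a LUT as CSV
#'
#' The CSV needs a `scalar,R,G,B` header.
#'
#' @param path CSV path.
#' @param units scalar units.
#' @export
read_lut_csv <- function(path, units = "um") {
  d <- utils::read.csv(path)
  need <- c("scalar", "R", "G", "B")
  if (!all(need %in% names(d)))
    stop("LUT CSV must have header scalar,R,G,B")
  color_lut(d$scalar, as.matrix(d[, c("R", "G", "B")]), units = units)
}

#' @rdname read_lut_csv
#' @param lut a `color_lut`.
#' @export
write_lut_csv <- function(lut, path) {
  utils::write.csv(data.frame(scalar = lut$values, R = lut$rgb[, 1],
                              G = lut$rgb[, 2], B = lut$rgb[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

# densely sampled LUT path: scalars and (unrounded) RGB at n samples
lut_path <- function(lut, n = 4096) {
  s <- seq(lut$range[1], lut$range[2], length.out = n)
  rgb <- vapply(1:3, function(k) {
    stats::approx(lut$values, lut$rgb[, k], xout = s)$y
  }, numeric(n))
  list(scalar = s, rgb = rgb)
}

#' Scalar quantization step of a LUT
#'
#' The scalar change corresponding to one 8-bit RGB quantum along the
#' slowest-varying LUT segment: the natural resolution limit of the codec
#' and the unit in which round-trip error is bounded.
#'
#' @param lut a `color_lut`.
#' @export
lut_quantization <- function(lut) {
  dv <- diff(lut$values)
  seglen <- sqrt(rowSums((lut$rgb[-1, , drop = FALSE] -
                          lut$rgb[-nrow(lut$rgb), , drop = FALSE])^2))
  max(dv / seglen)
}

#' Encode a scalar map as a 24-bit color image
#'
#' Per-pixel piecewise-linear interpolation of the LUT in RGB, rounded to
#' 8-bit channels. Out-of-range values are clamped; the clamped fraction is
#' attached as an attribute.
#'
#' @param map a [scalar_map] (or numeric matrix).
#' @param lut a `color_lut`.
#' @return `rows x cols x 3` integer array (0-255) with attribute
#'   `clamped_fraction`.
#' @export
encode_scalar_map <- function(map, lut) {
  v <- as.matrix(map)
  clamped <- mean(v < lut$range[1] | v > lut$range[2], na.rm = TRUE)
  v <- pmin(pmax(v, lut$range[1]), lut$range[2])
  out <- array(0L, c(dim(v), 3L))
  for (k in 1:3) {
    out[, , k] <- round(matrix(
      stats::approx(lut$values, lut$rgb[, k], xout = as.vector(v))$y,
      nrow(v), ncol(v)))
  }
  attr(out, "clamped_fraction") <- clamped
  out
}

#' Decode a 24-bit color map to a scalar map
#'
#' Each pixel is assigned the scalar of the nearest color (Euclidean RGB
#' distance) on the densely sampled LUT path; ties break toward the lower
#' scalar. Pixels farther than `tol` RGB units from the path are marked
#' invalid in the companion validity mask; if more than `max_invalid` of
#' pixels are invalid, decoding fails with the worst offending colors named.
#'
#' @param image `rows x cols x 3` array of 8-bit RGB (0-255), e.g. from
#'   [read_color_map] or [encode_scalar_map].
#' @param lut a `color_lut`.
#' @param n_path path samples for the nearest-color search (>= 4096).
#' @param tol RGB distance tolerance for validity (default 10).
#' @param max_invalid maximum tolerated invalid fraction (default 0.05).
#' @param pixel_pitch_um pitch metadata for the decoded map.
#' @return a [scalar_map] with attribute `valid` (logical matrix).
#' @export
decode_color_map <- function(image, lut, n_path = 4096, tol = 10,
                             max_invalid = 0.05, pixel_pitch_um = 10) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("image must be rows x cols x 3")
  path <- lut_path(lut, n_path)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  key <- px[, 1] * 65536 + px[, 2] * 256 + px[, 3]
  uk <- !duplicated(key)
  ucol <- px[uk, , drop = FALSE]
  # nearest path sample per unique color, chunked to bound memory
  n_u <- nrow(ucol)
  best_i <- integer(n_u)
  best_d <- numeric(n_u)
  p2 <- rowSums(path$rgb^2)
  chunk <- max(1L, floor(2e7 / n_path))
  for (s in seq(1L, n_u, by = chunk)) {
    e <- min(n_u, s + chunk - 1L)
    u <- ucol[s:e, , drop = FALSE]
    d2 <- outer(rowSums(u^2), p2, "+") - 2 * (u %*% t(path$rgb))
    i <- max.col(-d2, ties.method = "first")  # first = lower scalar
    best_i[s:e] <- i
    best_d[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), i)], 0))
  }
  idx <- match(key, key[uk])
  scal <- path$scalar[best_i][idx]
  dist <- best_d[idx]
  valid <- matrix(dist <= tol, dim(image)[1], dim(image)[2])
  if (mean(!valid) > max_invalid) {
    worst <- order(best_d, decreasing = TRUE)[seq_len(min(5, n_u))]
    stop(sprintf(
      "decoding failed: %.1f%% of pixels are off the LUT path; worst colors: %s",
      100 * mean(!valid),
      paste(apply(ucol[worst, , drop = FALSE], 1, paste, collapse = ","),
            collapse = " | ")))
  }
  out <- matrix(scal, dim(image)[1], dim(image)[2])
  out[!valid] <- NA
  m <- scalar_map(out, units = lut$units, pixel_pitch_um = pixel_pitch_um,
                  range = lut$range)
  attr(m, "valid") <- valid
  m
}
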