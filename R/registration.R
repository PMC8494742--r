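# Baseline <-> follow-up registration. Relative eye movement between visits
# is modelled as a 2-D affine transform solved by least squares from
# manually selected vessel-bifurcation control points, and follow-up maps
# are warped onto the baseline grid by inverse mapping with bilinear
# interpolation. Coordinates are 1-based pixel centres: pixel (row i, col j)
# sits at (x = j, y = i), origin top-left, x rightward, y downward.

#' Control-point set
#'
#' @param src,dst `n x 2` matrices of (x, y) coordinates with matching rows;
#'   at least 3 pairs, sources not collinear.
#' @param collinear_tol minimum normalized triangle area for the
#'   non-collinearity test.
#' @export
control_points <- function(src, dst, collinear_tol = 1e-8) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (ncol(src) != 2 || ncol(dst) != 2 || nrow(src) != nrow(dst))
    stop("src and dst must be n x 2 with matching rows")
  if (nrow(src) < 3) stop("at least 3 control-point pairs are required")
  if (is_collinear(src, collinear_tol))
    stop("source control points are collinear")
  structure(list(src = unname(src), dst = unname(dst)),
            class = "control_points")
}

is_collinear <- function(p, tol = 1e-8) {
  p <- sweep(p, 2, colMeans(p))
  s <- svd(p)$d
  s[2] <= tol * max(s[1], 1)
}

#' Read / write control points as CSV
#'
#' Header `src_x,src_y,dst_x,dst_y`.
#' @param path CSV path.
#' @export
read_control_points <- function(path) {
  d <- utils::read.csv(path)
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(d)))
    stop("control-point CSV must have header src_x,src_y,dst_x,dst_y")
  control_points(cbind(d$src_x, d$src_y), cbind(d$dst_x, d$dst_y))
}

#' @rdname read_control_points
#' @param points a `control_points` object.
#' @export
write_control_points <- function(points, path) {
  utils::write.csv(data.frame(src_x = points$src[, 1], src_y = points$src[, 2],
                              dst_x = points$dst[, 1], dst_y = points$dst[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Fit a 2-D affine transform from control points
#'
#' Least-squares solution of the overdetermined linear system mapping source
#' to target coordinates; with exactly 3 (non-collinear) pairs the fit
#' interpolates. The result is a 3 x 3 homogeneous matrix with last row
#' (0, 0, 1) acting on column vectors `(x, y, 1)`.
#'
#' @param points a [control_points] object.
#' @param residual_ceiling_px RMS residual above which a warning is issued.
#' @return an `affine2d` object: fields `matrix` and `rms_residual_px`.
#' @export
fit_affine <- function(points, residual_ceiling_px = 5) {
  X <- cbind(points$src, 1)
  coef <- tryCatch(qr.solve(X, points$dst),
                   error = function(e) stop("degenerate control points: ",
                                            conditionMessage(e)))
  M <- rbind(t(coef), c(0, 0, 1))
  fitted <- X %*% coef
  rms <- sqrt(mean((fitted - points$dst)^2))
  if (abs(det(M[1:2, 1:2])) < 1e-12) stop("fitted affine is singular")
  if (rms > residual_ceiling_px)
    warning(sprintf("registration residual %.2f px exceeds ceiling %g px",
                    rms, residual_ceiling_px))
  structure(list(matrix = unname(M), rms_residual_px = rms),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> rms residual", format(x$rms_residual_px, digits = 4),
      "px\n")
  print(x$matrix)
  invisible(x)
}

#' Build an affine transform from parameters
#'
#' Rotation (degrees, about the grid centre by default), isotropic scale and
#' translation — a convenience for simulating known motions.
#'
#' @param rotation_deg,scale,tx,ty transform parameters.
#' @param center `c(x, y)` rotation/scale centre.
#' @export
affine_from_params <- function(rotation_deg = 0, scale = 1, tx = 0, ty = 0,
                               center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  R <- scale * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  t0 <- c(center[1], center[2]) - R %*% c(center[1], center[2]) + c(tx, ty)
  M <- rbind(cbind(R, t0), c(0, 0, 1))
  structure(list(matrix = unname(M), rms_residual_px = 0), class = "affine2d")
}

#' Apply / invert an affine transform
#'
#' @param transform an `affine2d` (or bare 3 x 3 matrix).
#' @param xy `n x 2` matrix of (x, y) points.
#' @export
apply_affine <- function(transform, xy) {
  M <- if (inherits(transform, "affine2d")) transform$matrix else transform
  xy <- as.matrix(xy)
  out <- cbind(xy, 1) %*% t(M)
  out[, 1:2, drop = FALSE]
}

#' @rdname apply_affine
#' @export
invert_affine <- function(transform) {
  M <- if (inherits(transform, "affine2d")) transform$matrix else transform
  structure(list(matrix = solve(M), rms_residual_px = NA_real_),
            class = "affine2d")
}

#' Warp a map onto a target grid
#'
#' Inverse mapping: each target pixel (x, y) samples the input map at
#' `transform %*% (x, y, 1)` with bilinear (default) or nearest-neighbour
#' interpolation. Pixels whose sample footprint leaves the source grid are
#' invalid; the overlap mask marks valid pixels.
#'
#' @param map a [scalar_map] (or numeric matrix) to resample.
#' @param transform an `affine2d` mapping target-grid coordinates to map
#'   coordinates (for a follow-up map and control points picked as
#'   baseline -> follow-up, this is the fitted transform itself).
#' @param out_dim target grid `c(rows, cols)`; defaults to the map's.
#' @param interp `"bilinear"` or `"nearest"` (for label maps).
#' @return list with `map` (warped [scalar_map], NA outside overlap) and
#'   `overlap` (logical matrix).
#' @export
warp_map <- function(map, transform, out_dim = dim(as.matrix(map)),
                     interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  M <- if (inherits(transform, "affine2d")) transform$matrix else transform
  if (abs(det(M[1:2, 1:2])) < 1e-12) stop("degenerate transform")
  v <- unclass(as.matrix(map))
  nr <- nrow(v); nc <- ncol(v)
  gr <- out_dim[1]; gc <- out_dim[2]
  x <- rep(seq_len(gc), each = gr)   # column = x
  y <- rep(seq_len(gr), times = gc)  # row = y
  s <- cbind(x, y, 1) %*% t(M)
  xs <- s[, 1]; ys <- s[, 2]
  if (interp == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
    out <- rep(NA_real_, gr * gc)
    out[ok] <- v[cbind(yi[ok], xi[ok])]
  } else {
    ok <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
    x0 <- pmin(floor(xs), nc - 1); y0 <- pmin(floor(ys), nr - 1)
    fx <- xs - x0; fy <- ys - y0
    out <- rep(NA_real_, gr * gc)
    i <- which(ok)
    out[i] <- (1 - fx[i]) * (1 - fy[i]) * v[cbind(y0[i], x0[i])] +
              fx[i] * (1 - fy[i]) * v[cbind(y0[i], x0[i] + 1)] +
              (1 - fx[i]) * fy[i] * v[cbind(y0[i] + 1, x0[i])] +
              fx[i] * fy[i] * v[cbind(y0[i] + 1, x0[i] + 1)]
  }
  wm <- matrix(out, gr, gc)
  overlap <- matrix(!is.na(out), gr, gc)
  units <- attr(map, "units") %||% "um"
  list(map = scalar_map(wm, units = units,
                        pixel_pitch_um = attr(map, "pixel_pitch_um") %||% 10,
                        range = attr(map, "scalar_range")),
       overlap = overlap)
}

#' Write an affine transform as JSON
#' @param transform an `affine2d`.
#' @param path JSON path.
#' @export
write_affine_json <- function(transform, path) {
  jsonlite::write_json(list(matrix = transform$matrix,
                            rms_residual_px = transform$rms_residual_px),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
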