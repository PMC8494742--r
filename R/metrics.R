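# Region morphometry: physical area, percent of frame, mean vessel density
# and mean retinal thickness over any named region mask — the quantities
# tabulated per region in the study (areas in mm^2 and %, VD in %, MRT in um).

#' Physical area of a region mask
#'
#' @param mask a [region_mask] (or logical matrix).
#' @param pitch_um pixel pitch in micrometres (default: taken from the mask).
#' @return named numeric `c(area_mm2, area_pct)`.
#' @export
region_area <- function(mask, pitch_um = NULL) {
  pitch_um <- pitch_um %||% attr(mask, "pixel_pitch_um") %||% 10
  if (pitch_um <= 0) stop("pitch must be positive")
  m <- as_binary_matrix(mask)
  n <- sum(m)
  c(area_mm2 = n * (pitch_um / 1000)^2,
    area_pct = 100 * n / length(m))
}

#' Mean of a scalar map over a region mask
#'
#' Arithmetic mean of the map at TRUE pixels, in map units. Pixels marked
#' invalid (NA in the map, or FALSE in `valid`) are excluded and counted.
#' An empty mask yields `NA` with attribute `undefined = TRUE` rather than
#' a number.
#'
#' @param map a [scalar_map] (or numeric matrix).
#' @param mask a [region_mask] (or logical matrix) on the same grid.
#' @param valid optional validity matrix (e.g. from [decode_color_map]).
#' @export
mean_over_mask <- function(map, mask, valid = NULL) {
  check_same_grid(as.matrix(map), mask)
  m <- as_binary_matrix(mask)
  v <- unclass(as.matrix(map))
  if (is.null(valid)) valid <- attr(map, "valid")
  if (!is.null(valid)) v[!valid] <- NA
  vals <- v[m]
  excluded <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    return(structure(NA_real_, undefined = TRUE, n_excluded = excluded))
  }
  structure(mean(vals), undefined = FALSE, n_excluded = excluded,
            n_used = length(vals))
}

#' Vessel density recomputed from a binary vessel mask
#'
#' The study reads VD from the device's color-coded VD map; for phantoms a
#' recomputed alternative is available: the local vessel fraction (%) by a
#' normalized box filter over the binary vessel mask.
#'
#' @param vessels logical vessel mask.
#' @param window odd box-filter width in px (default 21).
#' @return a [scalar_map] in percent.
#' @export
vd_from_vessels <- function(vessels, window = 21, pixel_pitch_um = 10) {
  v <- as_binary_matrix(vessels) * 1
  k <- matrix(1 / window^2, window, window)
  f <- EBImage::imageData(EBImage::filter2(v, k, boundary = "replicate"))
  scalar_map(pmin(pmax(f, 0), 1) * 100, units = "percent",
             pixel_pitch_um = pixel_pitch_um, range = c(0, 100))
}

#' @rdname vd_from_vessels
#' @param pixel_pitch_um pitch metadata.
#' @name vd_from_vessels
NULL

#' Morphometry table over the named region system
#'
#' One row per region in [region_vocabulary] that is relevant per layer,
#' plus total-frame rows (`Total-SCP`, `Total-DCP`) that include the FAZ.
#' Missing regions yield a flagged row rather than an error.
#'
#' @param masks named list of [region_mask]s (names from the vocabulary).
#' @param vd named list with scalar VD maps `scp` and/or `dcp` (percent).
#' @param thickness retinal-thickness [scalar_map] (um).
#' @param pitch_um pixel pitch; defaults to the thickness map's.
#' @param eye_id identifier copied into every row.
#' @return a tibble with columns eye_id, region, present, pixel_count,
#'   area_mm2, area_pct, mean_vd_pct, mrt_um.
#' @export
metrics_table <- function(masks, vd, thickness, pitch_um = NULL,
                          eye_id = "case") {
  pitch_um <- pitch_um %||% attr(thickness, "pixel_pitch_um") %||% 10
  grid <- dim(as.matrix(thickness))
  order_regions <- c("SCP-A", "SCP-N", "SCP-C", "SCP-FAZ",
                     "DCP-A", "DCP-N", "DCP-C", "DCP-FAZ",
                     "TZ", "DCP-C&TZ", "DCP-C&SCP-A")
  vd_for <- function(region) {
    if (grepl("^SCP", region)) vd$scp else vd$dcp
  }
  one <- function(region, mask, vdmap) {
    if (is.null(mask)) {
      return(tibble::tibble(eye_id = eye_id, region = region,
                            present = FALSE, pixel_count = NA_integer_,
                            area_mm2 = NA_real_, area_pct = NA_real_,
                            mean_vd_pct = NA_real_, mrt_um = NA_real_))
    }
    ar <- region_area(mask, pitch_um)
    m <- as_binary_matrix(mask)
    tibble::tibble(
      eye_id = eye_id, region = region, present = TRUE,
      pixel_count = sum(m),
      area_mm2 = unname(ar["area_mm2"]), area_pct = unname(ar["area_pct"]),
      mean_vd_pct = if (is.null(vdmap)) NA_real_
                    else as.numeric(mean_over_mask(vdmap, m)),
      mrt_um = as.numeric(mean_over_mask(thickness, m)))
  }
  rows <- lapply(order_regions, function(r) one(r, masks[[r]], vd_for(r)))
  full <- matrix(TRUE, grid[1], grid[2])
  totals <- list(
    one("Total-SCP", region_mask(full, "SCP-N", pitch_um), vd$scp),
    one("Total-DCP", region_mask(full, "DCP-N", pitch_um), vd$dcp))
  totals[[1]]$region <- "Total-SCP"; totals[[2]]$region <- "Total-DCP"
  do.call(rbind, c(rows, totals))
}
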