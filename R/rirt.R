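# RIRT: the ratio of increased retinal thickness. After registering the
# follow-up thickness map onto the baseline grid, the per-pixel ratio
# follow-up / baseline is computed on the overlap. The macular-edema (ME)
# territory is the strict > 1.1 superlevel set (more than a 10% increase),
# presented as contours; apexes are local maxima of the smoothed ratio
# inside the territory, labelled by where they fall (FAZ / NPA / other).
# The eye-level recurrence rule is distinct and inclusive: CSMT increased
# by 10% or more from baseline.

#' Per-pixel ratio of increased retinal thickness
#'
#' Elementwise `followup / baseline` on the overlap; undefined (NA)
#' elsewhere. Zero-baseline pixels on the overlap are excluded and counted;
#' more than `max_zero_frac` of them is an error.
#'
#' @param baseline,warped_followup thickness [scalar_map]s (um) on one grid.
#' @param overlap logical validity mask (e.g. from [warp_map]).
#' @param max_zero_frac tolerated fraction of zero-baseline overlap pixels.
#' @return numeric matrix (dimensionless ratio) with attribute
#'   `n_zero_baseline`.
#' @export
compute_rirt <- function(baseline, warped_followup, overlap = NULL,
                         max_zero_frac = 0.10) {
  b <- unclass(as.matrix(baseline))
  f <- unclass(as.matrix(warped_followup))
  check_same_grid(b, f)
  if (is.null(overlap)) overlap <- !is.na(f)
  ov <- as_binary_matrix(overlap) & !is.na(b) & !is.na(f)
  zero <- ov & b <= 0
  if (sum(zero) > max_zero_frac * max(sum(ov), 1))
    stop(sprintf("%.1f%% of overlap pixels have zero baseline thickness",
                 100 * sum(zero) / max(sum(ov), 1)))
  r <- matrix(NA_real_, nrow(b), ncol(b))
  use <- ov & !zero
  r[use] <- f[use] / b[use]
  attr(r, "n_zero_baseline") <- sum(zero)
  r
}

#' Macular-edema territory and contours
#'
#' The territory is the strict superlevel set `rirt > threshold`
#' intersected with the overlap (a pixel exactly at the threshold is
#' excluded); contours are traced at the threshold level with
#' marching squares ([grDevices::contourLines]).
#'
#' @param rirt matrix from [compute_rirt].
#' @param threshold superlevel threshold (> 1); study value 1.1.
#' @return list with `territory` (logical matrix) and `contours` (list of
#'   data frames with x = column, y = row coordinates).
#' @export
me_territory <- function(rirt, threshold = 1.1) {
  if (threshold <= 1) stop("threshold must exceed 1")
  r <- as.matrix(rirt)
  territory <- !is.na(r) & r > threshold
  contours <- list()
  if (any(territory)) {
    zfill <- r
    zfill[is.na(zfill)] <- min(1, threshold - 0.5)
    cl <- grDevices::contourLines(x = seq_len(nrow(r)), y = seq_len(ncol(r)),
                                  z = zfill, levels = threshold)
    contours <- lapply(cl, function(ci) data.frame(x = ci$y, y = ci$x))
  }
  list(territory = territory, contours = contours)
}

#' Locate and classify RIRT apexes
#'
#' Local maxima of a Gaussian-smoothed copy of the RIRT map (sigma in px)
#' within the territory, ranked by value (ties broken by raster order:
#' by row, then column). Each apex is labelled `FAZ` if it falls in the
#' deep-layer FAZ mask, else `NPA` if inside the abnormal mask, else
#' `other`.
#'
#' @param rirt matrix from [compute_rirt].
#' @param territory logical ME-territory matrix.
#' @param faz,abnormal [region_mask]s (deep layer) for labelling.
#' @param sigma_px Gaussian smoothing sigma (default 2 px; 0 disables).
#' @return tibble with row, col, x, y, value (unsmoothed RIRT), label;
#'   zero rows when the territory is empty.
#' @export
locate_apexes <- function(rirt, territory, faz, abnormal, sigma_px = 2) {
  r <- as.matrix(rirt)
  terr <- as_binary_matrix(territory)
  empty <- tibble::tibble(row = integer(), col = integer(),
                          x = integer(), y = integer(),
                          value = numeric(), label = character())
  if (!any(terr)) return(empty)
  s <- r
  s[is.na(s)] <- 1
  if (sigma_px > 0)
    s <- EBImage::imageData(EBImage::gblur(s, sigma = sigma_px))
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- s
  ge_all <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ge_all <- ge_all & (s >= pad[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc])
  }
  cand <- ge_all & terr
  if (!any(cand)) return(empty)
  # collapse plateaus: one apex per connected candidate component,
  # at its first pixel in raster order (row-major)
  lab <- label_components8(cand)
  ids <- sort(unique(lab[lab > 0]))
  pick <- vapply(ids, function(id) {
    w <- which(lab == id)
    rr <- ((w - 1L) %% nr) + 1L
    cc <- ((w - 1L) %/% nr) + 1L
    w[order(rr, cc)[1]]
  }, integer(1))
  rr <- ((pick - 1L) %% nr) + 1L
  cc <- ((pick - 1L) %/% nr) + 1L
  f <- as_binary_matrix(faz)
  a <- as_binary_matrix(abnormal)
  label <- ifelse(f[pick], "FAZ", ifelse(a[pick], "NPA", "other"))
  val <- r[pick]
  ord <- order(-s[pick], rr, cc)
  tibble::tibble(row = rr[ord], col = cc[ord], x = cc[ord], y = rr[ord],
                 value = val[ord], label = label[ord])
}

#' Summary RIRT statistics over territory and congestion
#'
#' Mean and max of the RIRT over the ME territory and over DCP-C (each
#' intersected with the defined part of the map). Empty intersections give
#' NA entries flagged in `undefined`.
#'
#' @param rirt matrix from [compute_rirt].
#' @param territory logical ME-territory matrix.
#' @param dcp_c DCP congestion [region_mask].
#' @return tibble with region, mean_rirt, max_rirt, n_px, undefined.
#' @export
rirt_summary <- function(rirt, territory, dcp_c) {
  r <- as.matrix(rirt)
  one <- function(region, m) {
    m <- as_binary_matrix(m) & !is.na(r)
    if (!any(m)) {
      return(tibble::tibble(region = region, mean_rirt = NA_real_,
                            max_rirt = NA_real_, n_px = 0L,
                            undefined = TRUE))
    }
    tibble::tibble(region = region, mean_rirt = mean(r[m]),
                   max_rirt = max(r[m]), n_px = sum(m), undefined = FALSE)
  }
  rbind(one("ME-territory", territory), one("DCP-C", dcp_c))
}

#' Eye-level macular-edema recurrence rule
#'
#' Recurrent iff the central subfield macular thickness (CSMT) increased by
#' 10% or more from baseline (inclusive).
#'
#' @param csmt_baseline_um,csmt_followup_um CSMT in micrometres (> 0).
#' @return logical.
#' @export
classify_recurrence <- function(csmt_baseline_um, csmt_followup_um) {
  if (any(csmt_baseline_um <= 0) || any(csmt_followup_um <= 0))
    stop("CSMT values must be positive")
  (csmt_followup_um / csmt_baseline_um) >= (1.1 - 1e-12)
}

#' Central subfield macular thickness from a thickness map
#'
#' Mean thickness over the central disc of the given diameter (ETDRS central
#' subfield: 1 mm), centred on the grid centre (fovea-centred scans).
#'
#' @param thickness a thickness [scalar_map] (um).
#' @param diameter_mm central-subfield diameter (default 1 mm).
#' @export
csmt_from_map <- function(thickness, diameter_mm = 1) {
  pitch <- attr(thickness, "pixel_pitch_um") %||% 10
  v <- as.matrix(thickness)
  nr <- nrow(v); nc <- ncol(v)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r_px <- diameter_mm * 1000 / 2 / pitch
  xi <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  yi <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  disc <- (xi - cx)^2 + (yi - cy)^2 <= r_px^2
  as.numeric(mean_over_mask(v, disc))
}
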