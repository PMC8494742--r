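# Capillary congestion detection. The study defines congestion (SCP-C /
# DCP-C) as expanded, bright, coarse capillary networks between the affected
# and normal vasculature, judged on gamma-corrected (gamma = 3.0) 16-bit
# en-face OCTA: an expanded capillary has diameter > 2 px, a bright one has
# gray level >= 50% of full scale (32768), and a coarse one has a diameter
# that fluctuates by more than 2 px along the vessel. The detector makes
# those pixel rules operational: vessels are binarized, calibers measured at
# skeleton pixels from the Euclidean distance transform, and connected
# components qualifying under the rule are kept when they meet the
# abnormal/normal boundary band (never inside the FAZ).

#' Detection parameters for capillary congestion
#'
#' @param gamma gamma-correction exponent (study value 3.0).
#' @param bright_threshold 16-bit gray level for the brightness criterion
#'   (study value 32768, i.e. 50% of full scale).
#' @param expanded_caliber_px caliber above which a capillary counts as
#'   expanded; strict inequality (study value: exceeding 2 px).
#' @param coarse_fluctuation_px within-component caliber range above which a
#'   capillary counts as coarse; strict (study value: more than 2 px).
#' @param vessel_threshold binarization level applied to the gamma-corrected
#'   image for vessel extraction (default 13107 = 20% of full scale).
#' @param rule_mode how the three criteria combine: `"bright_and_expanded_or_coarse"`
#'   (default: bright AND (expanded OR coarse)), `"all"` (conjunction) or
#'   `"any"`.
#' @param boundary_band_px maximum distance (px) from the abnormal/normal
#'   interface for a component to qualify; 0 requires touching the interface.
#' @param speckle_min_px components smaller than this are removed as speckle.
#' @param brightness_stat component brightness statistic: `"median"`
#'   (default, robust) or `"mean"`.
#' @param brightness_on `"corrected"` (default: criterion judged on the
#'   gamma-corrected image, the study introduces gamma = 3.0 around these
#'   rules) or `"raw"`.
#' @export
congestion_params <- function(gamma = 3.0,
                              bright_threshold = 32768,
                              expanded_caliber_px = 2.0,
                              coarse_fluctuation_px = 2.0,
                              vessel_threshold = 13107,
                              rule_mode = c("bright_and_expanded_or_coarse",
                                            "all", "any"),
                              boundary_band_px = 20,
                              speckle_min_px = 5,
                              brightness_stat = c("median", "mean"),
                              brightness_on = c("corrected", "raw")) {
  stopifnot(gamma > 0, bright_threshold > 0, bright_threshold <= 65535,
            expanded_caliber_px > 0, coarse_fluctuation_px > 0,
            vessel_threshold >= 0, boundary_band_px >= 0)
  structure(list(gamma = gamma, bright_threshold = bright_threshold,
                 expanded_caliber_px = expanded_caliber_px,
                 coarse_fluctuation_px = coarse_fluctuation_px,
                 vessel_threshold = vessel_threshold,
                 rule_mode = match.arg(rule_mode),
                 boundary_band_px = boundary_band_px,
                 speckle_min_px = speckle_min_px,
                 brightness_stat = match.arg(brightness_stat),
                 brightness_on = match.arg(brightness_on)),
            class = "congestion_params")
}

#' Gamma correction of an en-face angiogram
#'
#' `out = round(65535 * (in / 65535)^(1/gamma))`: monotone and
#' endpoint-preserving; gamma > 1 brightens the mid-range, which is how the
#' boundary of capillary congestion is made visible on en-face OCTA.
#'
#' @param img an [enface_angiogram] or numeric matrix in `[0, 65535]`.
#' @param gamma positive exponent (study value 3.0).
#' @return same type as the input, gamma-corrected.
#' @export
gamma_correct <- function(img, gamma = 3.0) {
  if (gamma <= 0) stop("gamma must be positive")
  v <- round(65535 * (unclass(as.matrix(img)) / 65535)^(1 / gamma))
  if (inherits(img, "enface_angiogram")) {
    out <- img
    out[] <- v
    out
  } else v
}

# 8-connected component labelling via an igraph components pass over the
# pixel adjacency graph (EBImage::bwlabel is 4-connected).
label_components8 <- function(mask) {
  m <- as_binary_matrix(mask)
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  map <- integer(nr * nc)
  map[idx] <- seq_along(idx)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    rows <- max(1L, 1L - dr):min(nr, nr - dr)
    cols <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- m[rows, cols, drop = FALSE] & m[rows + dr, cols + dc, drop = FALSE]
    if (!any(a)) next
    w <- which(a)
    r0 <- ((w - 1L) %% length(rows)) + rows[1]
    c0 <- ((w - 1L) %/% length(rows)) + cols[1]
    i1 <- r0 + (c0 - 1L) * nr
    i2 <- (r0 + dr) + (c0 + dc - 1L) * nr
    edges[[length(edges) + 1L]] <- cbind(map[i1], map[i2])
  }
  ed <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(ed) > 0) g <- igraph::add_edges(g, t(ed))
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# Zhang-Suen morphological thinning to a 1-px (8-connected) skeleton.
skeletonize <- function(mask) {
  m <- as_binary_matrix(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  nb <- function(p, dr, dc) p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- pad
      # neighbours P2..P9 clockwise from north
      P2 <- nb(p, -1L, 0L); P3 <- nb(p, -1L, 1L); P4 <- nb(p, 0L, 1L)
      P5 <- nb(p, 1L, 1L);  P6 <- nb(p, 1L, 0L);  P7 <- nb(p, 1L, -1L)
      P8 <- nb(p, 0L, -1L); P9 <- nb(p, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      core <- p[2:(nr + 1L), 2:(nc + 1L)] & B >= 2 & B <= 6 & A == 1
      del <- if (sub == 1)
        core & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      else
        core & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      if (any(del)) {
        changed <- TRUE
        inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
        inner[del] <- FALSE
        pad[2:(nr + 1L), 2:(nc + 1L)] <- inner
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L)]
}

#' Extract the binary vessel mask from an angiogram
#'
#' Gamma-corrects the image, thresholds at `vessel_threshold`, and removes
#' 8-connected components below the speckle floor. When the threshold is 0
#' the whole frame is one component and the speckle floor does not apply.
#'
#' @param img an [enface_angiogram] or matrix in `[0, 65535]`.
#' @param params a [congestion_params].
#' @return logical matrix; attribute `empty` flags an all-FALSE result.
#' @export
extract_vessels <- function(img, params = congestion_params()) {
  g <- gamma_correct(img, params$gamma)
  v <- unclass(as.matrix(g)) >= params$vessel_threshold
  if (any(v) && !all(v) && params$speckle_min_px > 1) {
    lab <- label_components8(v)
    sizes <- tabulate(lab)
    keep <- which(sizes >= params$speckle_min_px)
    v <- matrix(lab %in% keep, nrow(v), ncol(v))
  }
  if (!any(v)) {
    attr(v, "empty") <- TRUE
    warning("vessel extraction produced an empty mask")
  } else attr(v, "empty") <- FALSE
  v
}

#' Per-skeleton-pixel vessel caliber (px)
#'
#' The vessel mask is thinned to its morphological skeleton; the caliber at
#' each skeleton pixel is `2 * d - 1` where `d` is the Euclidean distance to
#' the nearest background pixel, so an n-px-wide ribbon reads ~n px at its
#' centreline.
#'
#' @param vessels logical vessel mask (nonempty).
#' @return numeric matrix, caliber at skeleton pixels and `NA` elsewhere;
#'   attributes `skeleton` (logical matrix) and `distance` (EDT).
#' @export
estimate_calibers <- function(vessels) {
  v <- as_binary_matrix(vessels)
  if (!any(v)) stop("vessel mask is empty")
  d <- EBImage::imageData(EBImage::distmap(v * 1, metric = "euclidean"))
  sk <- skeletonize(v)
  cal <- matrix(NA_real_, nrow(v), ncol(v))
  cal[sk] <- 2 * d[sk] - 1
  attr(cal, "skeleton") <- sk
  attr(cal, "distance") <- d
  cal
}

# band of pixels within band_px of the abnormal/normal interface
boundary_band <- function(abnormal, normal, band_px) {
  a <- as_binary_matrix(abnormal)
  n <- as_binary_matrix(normal)
  k3 <- matrix(1, 3, 3)
  dil <- function(x, k) EBImage::imageData(EBImage::dilate(x * 1, k)) > 0
  interface <- (a & dil(n, k3)) | (n & dil(a, k3))
  if (band_px > 0 && any(interface)) {
    br <- EBImage::makeBrush(2 * ceiling(band_px) + 1, shape = "disc")
    interface <- dil(interface, br)
  }
  interface
}

#' Detect capillary congestion
#'
#' Vessel components (8-connected) are scored against the three pixel rules
#' — expanded (any skeleton caliber above `expanded_caliber_px`), bright
#' (component brightness statistic of the gamma-corrected image at or above
#' `bright_threshold`), coarse (within-component caliber range above
#' `coarse_fluctuation_px`) — and combined per `rule_mode`. Qualifying
#' components must intersect the band within `boundary_band_px` of the
#' abnormal/normal interface; the FAZ is always excluded. Returned as filled
#' component footprints.
#'
#' @param img an [enface_angiogram].
#' @param abnormal abnormal-region [region_mask] (same layer).
#' @param faz FAZ [region_mask] (same layer).
#' @param params a [congestion_params].
#' @param layer layer tag for the output mask name (`"DCP"` or `"SCP"`).
#' @return congestion [region_mask]; attribute `component_stats` is a tibble
#'   of per-component criteria.
#' @export
detect_congestion <- function(img, abnormal, faz,
                              params = congestion_params(),
                              layer = c("DCP", "SCP")) {
  layer <- match.arg(layer)
  check_same_grid(as.matrix(img), abnormal, faz)
  pitch <- attr(img, "pixel_pitch_um") %||% 10
  empty <- function() {
    region_mask(matrix(FALSE, nrow(img), ncol(img)),
                paste0(layer, "-C"), pitch)
  }
  vessels <- suppressWarnings(extract_vessels(img, params))
  if (!any(vessels)) return(empty())
  lab <- label_components8(vessels)
  cal <- estimate_calibers(vessels)
  g <- unclass(gamma_correct(as.matrix(img), params$gamma))
  raw <- unclass(as.matrix(img))
  bsrc <- if (params$brightness_on == "corrected") g else raw
  a <- as_binary_matrix(abnormal)
  f <- as_binary_matrix(faz)
  normal <- !a & !f
  band <- boundary_band(a, normal, params$boundary_band_px)

  labv <- as.vector(lab)
  inmask <- labv > 0
  ids <- sort(unique(labv[inmask]))
  fl <- factor(labv[inmask], levels = ids)
  stat_fun <- if (params$brightness_stat == "median") stats::median else mean
  bright_stat <- vapply(split(bsrc[inmask], fl), stat_fun, numeric(1))
  sk <- attr(cal, "skeleton")
  sk_fl <- factor(lab[sk], levels = ids)
  sk_cal <- cal[sk]
  cal_max <- vapply(split(sk_cal, sk_fl),
                    function(z) if (length(z)) max(z) else NA_real_,
                    numeric(1))
  cal_rng <- vapply(split(sk_cal, sk_fl),
                    function(z) if (length(z)) diff(range(z)) else 0,
                    numeric(1))
  touches <- vapply(split(band[inmask], fl), any, logical(1))

  expanded <- !is.na(cal_max) & cal_max > params$expanded_caliber_px
  coarse <- cal_rng > params$coarse_fluctuation_px
  bright <- bright_stat >= params$bright_threshold
  qual <- switch(params$rule_mode,
    bright_and_expanded_or_coarse = bright & (expanded | coarse),
    all = bright & expanded & coarse,
    any = bright | expanded | coarse)
  qual <- qual & touches

  out <- matrix(lab %in% ids[qual], nrow(img), ncol(img))
  if (any(out)) out <- EBImage::imageData(EBImage::fillHull(out * 1)) > 0
  out <- out & !f
  res <- region_mask(out, paste0(layer, "-C"), pitch)
  attr(res, "component_stats") <- tibble::tibble(
    component = ids, n_px = as.integer(table(fl)),
    bright_stat = as.numeric(bright_stat), caliber_max = cal_max,
    caliber_range = cal_rng, bright = as.logical(bright),
    expanded = expanded, coarse = coarse,
    touches_boundary = as.logical(touches), qualifies = as.logical(qual))
  res
}
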