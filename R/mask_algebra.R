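# Region-mask algebra. The study's region system per plexus layer is a
# partition {abnormal (A), normal (N), FAZ}: N is the complement of A except
# the FAZ. The transitional zone TZ is abnormal DCP under normal SCP
# (elementwise product of SCP-N and DCP-A), and the deep congestion DCP-C is
# split into the part inside TZ and the part under SCP-A, with an explicit
# residual class as a consistency check (in the study's scheme the residual
# is empty because DCP-C lies within DCP-A).

#' Normal region of a plexus layer
#'
#' `N = NOT(A OR FAZ)`. If the abnormal mask overlaps the FAZ the overlap is
#' removed from A first (the FAZ is excluded from all abnormal selections);
#' the repair is flagged via the `faz_overlap_repaired` attribute carrying
#' the number of repaired pixels.
#'
#' @param abnormal,faz [region_mask]s (or logical matrices) on one grid.
#' @param layer `"SCP"` or `"DCP"`, used to name the output.
#' @return the normal-region [region_mask]; attribute `abnormal_repaired`
#'   holds the (possibly repaired) abnormal mask.
#' @export
normal_region <- function(abnormal, faz, layer = c("DCP", "SCP")) {
  layer <- match.arg(layer)
  check_same_grid(abnormal, faz)
  a <- as_binary_matrix(abnormal)
  f <- as_binary_matrix(faz)
  n_overlap <- sum(a & f)
  if (n_overlap > 0) a <- a & !f
  pitch <- attr(abnormal, "pixel_pitch_um") %||% 10
  out <- region_mask(!(a | f), paste0(layer, "-N"), pitch)
  attr(out, "faz_overlap_repaired") <- n_overlap
  attr(out, "abnormal_repaired") <-
    region_mask(a, paste0(layer, "-A"), pitch)
  out
}

#' Transitional zone
#'
#' Abnormal DCP under normal SCP: the elementwise (Hadamard) product of the
#' SCP normal mask and the DCP abnormal mask. By construction `TZ` is a
#' subset of DCP-A and disjoint from SCP-A.
#'
#' @param scp_n,dcp_a [region_mask]s on one grid.
#' @export
transitional_zone <- function(scp_n, dcp_a) {
  check_same_grid(scp_n, dcp_a)
  pitch <- attr(dcp_a, "pixel_pitch_um") %||% 10
  region_mask(as_binary_matrix(scp_n) & as_binary_matrix(dcp_a), "TZ", pitch)
}

#' Partition the deep capillary congestion
#'
#' Splits DCP-C pixels into the part inside the transitional zone, the part
#' under SCP-A, and a residual class (pixels in neither). Pixel counts are
#' conserved exactly; the residual fraction is reported and should be ~0
#' whenever DCP-C lies within DCP-A, which the study's scheme implies.
#'
#' @param dcp_c,tz,scp_a [region_mask]s on one grid.
#' @param dcp_a optional DCP-A mask; if given, the residual check also
#'   reports the fraction of DCP-C outside DCP-A.
#' @return list with masks `in_tz`, `under_scp_a`, `residual`, counts, and
#'   `residual_fraction`.
#' @export
partition_dcp_congestion <- function(dcp_c, tz, scp_a, dcp_a = NULL) {
  check_same_grid(dcp_c, tz, scp_a)
  c_ <- as_binary_matrix(dcp_c)
  t_ <- as_binary_matrix(tz)
  s_ <- as_binary_matrix(scp_a)
  pitch <- attr(dcp_c, "pixel_pitch_um") %||% 10
  in_tz <- c_ & t_
  under <- c_ & s_ & !t_
  resid <- c_ & !in_tz & !under
  n_c <- sum(c_)
  out <- list(
    in_tz = region_mask(in_tz, "DCP-C&TZ", pitch),
    under_scp_a = region_mask(under, "DCP-C&SCP-A", pitch),
    residual = region_mask(resid, "residual", pitch),
    counts = c(dcp_c = n_c, in_tz = sum(in_tz), under_scp_a = sum(under),
               residual = sum(resid)),
    residual_fraction = if (n_c > 0) sum(resid) / n_c else 0
  )
  if (!is.null(dcp_a)) {
    check_same_grid(dcp_c, dcp_a)
    out$outside_dcp_a_fraction <-
      if (n_c > 0) sum(c_ & !as_binary_matrix(dcp_a)) / n_c else 0
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
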