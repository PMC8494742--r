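# End-to-end orchestration: decode -> segment -> mask algebra -> metrics,
# and when a follow-up visit is present, register -> RIRT -> territory ->
# apexes -> recurrence. `run_case` operates on one eye (a phantom case or
# equivalent inputs); `run_cohort` runs the statistical layer on a cohort
# table (simulated or user-supplied).

#' Run the single-case pipeline
#'
#' Stages: encode/decode the thickness and VD maps through the color-map
#' codec (exercising the conversion step the device software performs),
#' detect deep capillary congestion, derive the named region system,
#' compute the morphometry table, and — when a follow-up thickness map is
#' present — fit the affine from control points, warp the follow-up onto
#' the baseline grid, compute the RIRT map, ME territory, apexes, summary
#' and the eye-level recurrence call. Deterministic for fixed inputs.
#'
#' @param case a `phantom_case` (from [generate_phantom_case]), or a list
#'   with the same fields; `thickness_followup` and `control_points` are
#'   optional (their absence skips the RIRT stage).
#' @param params a [congestion_params].
#' @param thickness_lut,vd_lut LUTs for the codec stage.
#' @param use_codec route the scalar maps through encode/decode (default
#'   TRUE); FALSE uses them directly.
#' @param out_dir optional directory: artifacts and a JSON report are
#'   written when given.
#' @param eye_id identifier used in tables.
#' @return a `case_report` list: `masks`, `metrics`, `detected_dcp_c`,
#'   and (if follow-up present) `registration`, `rirt`, `territory`,
#'   `apexes`, `rirt_summary`, `recurrence`.
#' @export
run_case <- function(case, params = congestion_params(),
                     thickness_lut = default_thickness_lut(),
                     vd_lut = default_vd_lut(),
                     use_codec = TRUE, out_dir = NULL, eye_id = "case") {
  pitch <- attr(case$dcp, "pixel_pitch_um") %||% 10
  dec <- function(map, lut) {
    if (!use_codec) return(map)
    decode_color_map(encode_scalar_map(map, lut), lut,
                     pixel_pitch_um = pitch)
  }
  thickness <- dec(case$thickness_baseline, thickness_lut)
  vd_dcp <- dec(case$vd$dcp, vd_lut)
  vd_scp <- if (!is.null(case$vd$scp)) dec(case$vd$scp, vd_lut) else NULL

  m <- case$truth$masks
  dcp_n <- normal_region(m[["DCP-A"]], m[["DCP-FAZ"]], layer = "DCP")
  scp_n <- normal_region(m[["SCP-A"]], m[["SCP-FAZ"]], layer = "SCP")
  tz <- transitional_zone(scp_n, m[["DCP-A"]])
  dcp_c <- detect_congestion(case$dcp, m[["DCP-A"]], m[["DCP-FAZ"]],
                             params, layer = "DCP")
  part <- partition_dcp_congestion(dcp_c, tz, m[["SCP-A"]], m[["DCP-A"]])

  masks <- list("SCP-A" = m[["SCP-A"]], "SCP-N" = scp_n,
                "SCP-C" = m[["SCP-C"]], "SCP-FAZ" = m[["SCP-FAZ"]],
                "DCP-A" = m[["DCP-A"]], "DCP-N" = dcp_n,
                "DCP-C" = dcp_c, "DCP-FAZ" = m[["DCP-FAZ"]],
                "TZ" = tz, "DCP-C&TZ" = part$in_tz,
                "DCP-C&SCP-A" = part$under_scp_a)
  metrics <- metrics_table(masks, list(scp = vd_scp, dcp = vd_dcp),
                           thickness, pitch, eye_id = eye_id)
  report <- list(eye_id = eye_id, masks = masks, metrics = metrics,
                 detected_dcp_c = dcp_c, congestion_partition = part$counts,
                 params = params)

  has_followup <- !is.null(case$thickness_followup) &&
    !is.null(case$control_points)
  if (has_followup) {
    tfm <- fit_affine(case$control_points)
    followup <- dec(case$thickness_followup, thickness_lut)
    w <- warp_map(followup, tfm)
    rirt <- compute_rirt(thickness, w$map, w$overlap)
    terr <- me_territory(rirt, threshold = 1.1)
    apexes <- locate_apexes(rirt, terr$territory, m[["DCP-FAZ"]],
                            m[["DCP-A"]])
    summ <- rirt_summary(rirt, terr$territory, dcp_c)
    csmt_b <- csmt_from_map(thickness)
    csmt_f <- csmt_from_map(scalar_map(ifelse(w$overlap,
                                              as.matrix(w$map), NA),
                                       "um", pitch))
    report$registration <- tfm
    report$rirt <- rirt
    report$territory <- terr$territory
    report$contours <- terr$contours
    report$apexes <- apexes
    report$rirt_summary <- summ
    report$recurrence <- list(
      csmt_baseline_um = csmt_b, csmt_followup_um = csmt_f,
      recurrent = classify_recurrence(csmt_b, csmt_f))
  }
  class(report) <- "case_report"
  if (!is.null(out_dir)) write_case_report(report, out_dir)
  report
}

write_case_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  utils::write.csv(report$metrics, fp("metrics.csv"), row.names = FALSE)
  save_mask(report$detected_dcp_c, fp("detected_dcp_c.png"))
  j <- list(eye_id = report$eye_id,
            congestion_partition = as.list(report$congestion_partition))
  if (!is.null(report$rirt)) {
    write_float_map(report$rirt, fp("rirt.tif"))
    save_mask(report$territory, fp("me_territory.png"))
    j$registration <- list(matrix = report$registration$matrix,
                           rms_residual_px = report$registration$rms_residual_px)
    j$apexes <- report$apexes
    j$rirt_summary <- report$rirt_summary
    j$recurrence <- report$recurrence
  }
  jsonlite::write_json(j, fp("report.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(out_dir)
}

#' Run the cohort statistical layer
#'
#' Produces the study-shaped outputs: group comparisons of baseline and
#' imaging covariates between recurrence and non-recurrence eyes
#' (Mann-Whitney for numeric, chi-squared/Fisher for categorical),
#' univariate logistic screening of candidate risk factors, a multivariate
#' model over the univariately significant terms, and odds-ratio
#' derivations for each multivariate term with OR > 1.
#'
#' @param cohort tibble from [simulate_cohort] or a user CSV with the same
#'   columns (at minimum: `recurrent` plus the candidate terms).
#' @param terms candidate risk-factor columns.
#' @param alpha univariate screening level for the multivariate step.
#' @return a `cohort_report` list of tibbles: `comparisons`, `univariate`,
#'   `multivariate`, `or_derivations`.
#' @export
run_cohort <- function(cohort,
                       terms = c("age_years", "period_to_baseline_months",
                                 "n_injections_total", "dcp_c_mrt_um"),
                       alpha = 0.05) {
  if (!"recurrent" %in% names(cohort)) stop("cohort lacks 'recurrent'")
  rec <- as.logical(cohort$recurrent)
  if (all(rec) || all(!rec))
    stop("one outcome group is empty (grouping variable: recurrent)")
  num_terms <- terms[vapply(cohort[terms], is.numeric, logical(1))]
  comparisons <- do.call(rbind, lapply(num_terms, function(v) {
    ct <- compare_groups(cohort[[v]][!rec], cohort[[v]][rec],
                         test = "mann_whitney")
    ct$variable <- v
    ct$mean_nonrecurrence <- mean(cohort[[v]][!rec], na.rm = TRUE)
    ct$mean_recurrence <- mean(cohort[[v]][rec], na.rm = TRUE)
    ct
  }))
  uni <- logistic_fit(cohort, "recurrent", terms, mode = "univariate")
  sel <- select_multivariate_terms(uni, alpha)
  multi <- if (length(sel) >= 1)
    logistic_fit(cohort, "recurrent", sel, mode = "multivariate")
  else uni[0, ]
  ors <- do.call(rbind, lapply(seq_len(nrow(multi)), function(i) {
    if (!is.na(multi$odds_ratio[i]) && multi$odds_ratio[i] > 1) {
      d <- or_derivations(multi$odds_ratio[i])
      tibble::tibble(term = multi$term[i], odds_ratio = multi$odds_ratio[i],
                     pct_increase_per_unit = d$pct_increase_per_unit,
                     doubling_units = d$doubling_units)
    } else NULL
  }))
  structure(list(comparisons = comparisons, univariate = uni,
                 multivariate = multi, or_derivations = ors),
            class = "cohort_report")
}
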