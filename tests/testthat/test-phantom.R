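test_that("phantom generation is deterministic under the seed", {
  a <- generate_phantom_case(small_phantom_config(seed = 3))
  b <- generate_phantom_case(small_phantom_config(seed = 3))
  expect_identical(as.matrix(a$dcp), as.matrix(b$dcp))
  expect_identical(a$truth$true_edema_territory, b$truth$true_edema_territory)
  expect_identical(a$control_points$src, b$control_points$src)
  c_ <- generate_phantom_case(small_phantom_config(seed = 4))
  expect_false(identical(as.matrix(a$dcp), as.matrix(c_$dcp)))
})

test_that("no edema means an empty true territory", {
  cfg <- small_phantom_config(
    seed = 5, edema = list(center_xy = NULL, peak_ratio = 1.0,
                           radius_um = 1500))
  case <- generate_phantom_case(cfg)
  expect_false(any(case$truth$true_edema_territory))
})

test_that("the true territory is the analytic superlevel set of the blob", {
  cfg <- small_phantom_config(
    seed = 6,
    motion = affine_from_params(),  # identity
    edema = list(center_xy = c(100.5, 100.5), peak_ratio = 1.5,
                 radius_um = 50 * 30))  # 50-px blob radius
  case <- generate_phantom_case(cfg)
  g <- expand.grid(y = 1:200, x = 1:200)
  rr <- sqrt((g$x - 100.5)^2 + (g$y - 100.5)^2)
  ratio <- rep(1, 200 * 200)
  inside <- rr < 50
  ratio[inside] <- 1 + 0.5 * 0.5 * (1 + cos(pi * rr[inside] / 50))
  expect_identical(case$truth$true_edema_territory,
                   matrix(ratio > 1.1, 200, 200))
})

test_that("ground-truth masks satisfy the region-system invariants", {
  for (seed in c(1, 9, 23)) {
    m <- generate_phantom_case(small_phantom_config(seed = seed))$truth$masks
    lm <- lapply(m, function(x) matrix(as.logical(x), nrow(x), ncol(x)))
    for (layer in c("SCP", "DCP")) {
      a <- lm[[paste0(layer, "-A")]]
      nr <- lm[[paste0(layer, "-N")]]
      fz <- lm[[paste0(layer, "-FAZ")]]
      expect_equal(sum(a) + sum(nr) + sum(fz), length(a))
      expect_false(any(a & nr) || any(a & fz) || any(nr & fz))
    }
    expect_true(all(lm[["DCP-A"]][lm[["SCP-A"]]]))           # strict containment
    expect_gt(sum(lm[["DCP-A"]]), sum(lm[["SCP-A"]]))
    expect_identical(lm[["TZ"]], lm[["SCP-N"]] & lm[["DCP-A"]])
    expect_true(all(lm[["DCP-A"]][lm[["DCP-C"]]]))           # DCP-C inside DCP-A
    expect_false(any(lm[["DCP-C"]] & lm[["DCP-FAZ"]]))
    # corridor reaches the abnormal/normal boundary region
    band <- octacongest:::boundary_band(lm[["DCP-A"]],
                                        lm[["DCP-N"]], 5)
    expect_true(any(band & lm[["DCP-C"]]))
  }
})

test_that("follow-up thickness is baseline composed with edema and motion", {
  case <- small_phantom_case()
  cfg <- case$truth$config
  M <- case$truth$true_affine$matrix
  # spot-check: evaluate the generating fields at M^{-1} of follow-up pixels
  Minv <- solve(M)
  pts <- rbind(c(60, 60), c(100, 140), c(150, 80))
  for (k in seq_len(nrow(pts))) {
    xy <- pts[k, ]
    q <- (Minv %*% c(xy, 1))[1:2]
    B <- octacongest:::baseline_thickness_at(q[1], q[2], cfg)
    E <- octacongest:::edema_ratio_at(q[1], q[2], c(100.5, 100.5),
                                      cfg$edema$radius_um / 30,
                                      cfg$edema$peak_ratio)
    expect_equal(as.matrix(case$thickness_followup)[xy[2], xy[1]], B * E,
                 tolerance = 1e-9)
  }
})

test_that("inconsistent geometry is rejected", {
  expect_error(phantom_config(grid_size = 100, pixel_pitch_um = 10,
                              dcp_faz_radius_um = 600),
               "geometry")
  expect_error(phantom_config(abnormal_inner_radius_um = 300),
               "geometry")
  expect_error(phantom_config(npa_width_scp_deg = 150,
                              npa_width_dcp_deg = 130))
})

test_that("simulated cohorts follow the configured logistic model", {
  # null model: recurrence fraction ~ 1/2
  null_cfg <- cohort_sim_config(n_eyes = 2000, beta0 = 0, beta_mrt = 0,
                                beta_inject = 0, seed = 71)
  coh <- simulate_cohort(null_cfg)
  expect_equal(mean(coh$recurrent), 0.5, tolerance = 0.05)
  # saturation: a very negative intercept kills all recurrences
  sat <- cohort_sim_config(n_eyes = 200, beta0 = -60, beta_mrt = 0,
                           beta_inject = 0, seed = 72)
  expect_warning(coh2 <- simulate_cohort(sat), "degenerate")
  expect_equal(sum(coh2$recurrent), 0)
  expect_true(attr(coh2, "degenerate"))
  # reproducibility and recurrence-only fields
  c1 <- simulate_cohort(cohort_sim_config(seed = 73))
  c2 <- simulate_cohort(cohort_sim_config(seed = 73))
  expect_identical(c1$recurrent, c2$recurrent)
  expect_true(all(is.na(c1$period_to_recurrence_months[!c1$recurrent])))
  expect_true(all(!is.na(c1$csmt_at_recurrence_um[c1$recurrent])))
  expect_true(all(c1$csmt_at_recurrence_um[c1$recurrent] >=
                  1.1 * c1$csmt_um[c1$recurrent]))
})

test_that("a written phantom case round-trips through the raster formats", {
  case <- small_phantom_case()
  dir <- withr::local_tempdir()
  write_phantom_case(case, dir)
  dcp <- read_angiogram(file.path(dir, "dcp.tif"), layer = "DCP",
                        pixel_pitch_um = 30)
  expect_equal(matrix(as.numeric(dcp), 200, 200),
               matrix(as.numeric(case$dcp), 200, 200))
  th <- read_scalar_map(file.path(dir, "thickness_baseline.tif"))
  expect_lt(max(abs(as.matrix(th) - as.matrix(case$thickness_baseline))),
            500 / 65535 + 1e-9)
  mk <- load_mask(file.path(dir, "mask_DCP_C.png"), "DCP-C", 30)
  expect_identical(matrix(as.logical(mk), 200, 200),
                   matrix(as.logical(case$truth$masks[["DCP-C"]]), 200, 200))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$true_affine, case$truth$true_affine$matrix,
               tolerance = 1e-12)
})
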