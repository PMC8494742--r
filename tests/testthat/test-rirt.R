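test_that("RIRT is the pixelwise follow-up/baseline ratio on the overlap", {
  b <- matrix(200, 12, 12)
  expect_true(all(compute_rirt(b, b) == 1))
  f <- matrix(300, 12, 12)
  expect_true(all(compute_rirt(b, f) == 1.5))
  withr::with_seed(61, {
    b2 <- matrix(runif(100, 150, 350), 10, 10)
    f2 <- matrix(runif(100, 150, 500), 10, 10)
    r <- compute_rirt(b2, f2)
    for (i in 1:10) for (j in 1:10)
      expect_identical(r[i, j], f2[i, j] / b2[i, j])
  })
})

test_that("zero-baseline pixels are excluded, many of them are an error", {
  b <- matrix(200, 10, 10); b[1, 1] <- 0
  f <- matrix(220, 10, 10)
  r <- compute_rirt(b, f)
  expect_true(is.na(r[1, 1]))
  expect_equal(attr(r, "n_zero_baseline"), 1)
  b[1:3, ] <- 0
  expect_error(compute_rirt(b, f), "zero baseline")
})

test_that("territory uses a strict superlevel threshold", {
  r <- matrix(1.0, 8, 8)
  t0 <- me_territory(r)
  expect_false(any(t0$territory))
  expect_length(t0$contours, 0)
  r[4, 4] <- 1.1   # exactly at threshold: excluded
  expect_false(any(me_territory(r, 1.1)$territory))
  r[4, 4] <- 1.1 + 1e-9
  expect_true(me_territory(r, 1.1)$territory[4, 4])
  expect_error(me_territory(r, 1.0), "exceed 1")
})

test_that("territory of a raised-cosine blob matches the analytic level set", {
  n <- 120; peak <- 1.5; radius <- 40
  g <- expand.grid(y = 1:n, x = 1:n)
  rr <- sqrt((g$x - 60.5)^2 + (g$y - 60.5)^2)
  rirt <- matrix(1, n, n)
  inside <- rr < radius
  rirt[inside] <- 1 + (peak - 1) * 0.5 * (1 + cos(pi * rr[inside] / radius))
  terr <- me_territory(rirt, 1.1)$territory
  # closed-form superlevel disc: ratio > 1.1 iff r < R/pi * acos(2*0.1/(peak-1) - 1)
  r_star <- radius / pi * acos(2 * 0.1 / (peak - 1) - 1)
  analytic <- matrix(rr < r_star, n, n)
  expect_true(all(terr == analytic | abs(rr - r_star) <= 1))
  # monotone nesting in the threshold
  t12 <- me_territory(rirt, 1.2)$territory
  t13 <- me_territory(rirt, 1.3)$territory
  expect_true(all(!t12 | terr))
  expect_true(all(!t13 | t12))
})

test_that("apexes are located and labelled by region membership", {
  n <- 100
  g <- expand.grid(y = 1:n, x = 1:n)
  blob <- function(cx, cy, peak, rad) {
    rr <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
    v <- rep(1, n * n)
    v[rr < rad] <- 1 + (peak - 1) * 0.5 * (1 + cos(pi * rr[rr < rad] / rad))
    matrix(v, n, n)
  }
  faz <- matrix(FALSE, n, n); faz[(g$x - 50)^2 + (g$y - 50)^2 <= 15^2] <- TRUE
  npa <- matrix(FALSE, n, n); npa[, 75:100] <- TRUE
  # blob centred in the FAZ
  r1 <- blob(50, 50, 1.6, 20)
  a1 <- locate_apexes(r1, me_territory(r1)$territory, faz, npa)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$label, "FAZ")
  expect_lte(max(abs(c(a1$x - 50, a1$y - 50))), 1)
  # blob in the abnormal region
  r2 <- blob(85, 30, 1.6, 12)
  a2 <- locate_apexes(r2, me_territory(r2)$territory, faz, npa)
  expect_equal(a2$label, "NPA")
  # blob in neither
  r3 <- blob(20, 80, 1.6, 12)
  a3 <- locate_apexes(r3, me_territory(r3)$territory, faz, npa)
  expect_equal(a3$label, "other")
  # two equal blobs: two apexes, deterministic raster order among ties
  r4 <- pmax(blob(30, 30, 1.5, 10), blob(70, 70, 1.5, 10))
  a4 <- locate_apexes(r4, me_territory(r4)$territory, faz, npa)
  expect_equal(nrow(a4), 2)
  expect_true(a4$row[1] <= a4$row[2])
  # empty territory gives an empty list
  a0 <- locate_apexes(matrix(1, 10, 10), matrix(FALSE, 10, 10),
                      faz[1:10, 1:10], npa[1:10, 1:10])
  expect_equal(nrow(a0), 0)
})

test_that("summary statistics honour masks and flag empty intersections", {
  r <- matrix(1.25, 15, 15)
  terr <- matrix(TRUE, 15, 15)
  dcp_c <- matrix(FALSE, 15, 15); dcp_c[2:4, 2:4] <- TRUE
  s <- rirt_summary(r, terr, dcp_c)
  expect_equal(s$mean_rirt, c(1.25, 1.25))
  expect_equal(s$max_rirt, c(1.25, 1.25))
  s2 <- rirt_summary(r, terr, matrix(FALSE, 15, 15))
  expect_true(s2$undefined[s2$region == "DCP-C"])
  # max over the territory dominates the max over any subset
  withr::with_seed(62, {
    rr <- matrix(runif(225, 1, 2), 15, 15)
    sub <- random_mask(15, 0.3)
    s3 <- rirt_summary(rr, terr, sub & terr)
    expect_gte(s3$max_rirt[1], s3$max_rirt[2])
  })
})

test_that("recurrence rule is inclusive at a 10% CSMT increase", {
  expect_true(classify_recurrence(300, 330))    # exact boundary
  expect_false(classify_recurrence(250, 250))
  expect_true(classify_recurrence(226.4, 362.2))
  expect_false(classify_recurrence(300, 329.9))
  expect_error(classify_recurrence(0, 300), "positive")
})

test_that("phantom territory reproduces the generating edema field", {
  case <- small_phantom_case()
  cp <- fit_affine(case$control_points)
  w <- warp_map(case$thickness_followup, cp)
  rirt <- compute_rirt(case$thickness_baseline, w$map, w$overlap)
  terr <- me_territory(rirt, 1.1)$territory
  truth <- case$truth$true_edema_territory
  ov <- w$overlap
  # any disagreement must sit within 1 px of the true territory boundary
  k3 <- matrix(1, 3, 3)
  dil <- EBImage::imageData(EBImage::dilate(truth * 1, k3)) > 0
  ero <- EBImage::imageData(EBImage::erode(truth * 1, k3)) > 0
  boundary_band <- dil & !ero
  mismatch <- (terr != truth) & ov
  expect_true(all(boundary_band[mismatch]))
})
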