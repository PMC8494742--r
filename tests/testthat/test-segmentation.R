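test_that("gamma correction preserves endpoints and is the identity at 1", {
  m <- matrix(c(0, 65535, 32768, 1000), 2, 2)
  g <- gamma_correct(m, 3.0)
  expect_equal(g[1, 1], 0)
  expect_equal(g[2, 1], 65535)
  # closed form at ~half scale
  expect_equal(g[1, 2], round(65535 * (32768 / 65535)^(1 / 3)))
  expect_equal(gamma_correct(m, 1.0), m)
  expect_error(gamma_correct(m, 0), "positive")
})

test_that("gamma correction is monotone nondecreasing for any gamma > 0", {
  v <- matrix(seq(0, 65535, length.out = 200), 1)
  for (g in c(0.5, 1, 2.2, 3, 10)) {
    expect_true(all(diff(as.vector(gamma_correct(v, g))) >= 0))
  }
})

test_that("vessel extraction handles degenerate inputs", {
  zero <- matrix(0, 32, 32)
  expect_warning(v <- extract_vessels(zero), "empty")
  expect_false(any(v))
  # threshold 0: everything is vessel, one component, speckle floor moot
  p0 <- congestion_params(vessel_threshold = 0)
  v0 <- extract_vessels(matrix(100, 32, 32), p0)
  expect_true(all(v0))
})

test_that("vessel extraction recovers the phantom network", {
  case <- small_phantom_case()
  v <- extract_vessels(case$dcp)
  gt <- case$truth$dcp_vessels
  iou <- sum(v & gt) / sum(v | gt)
  expect_gte(iou, 0.9)
})

test_that("caliber estimates match ribbon, line and disc oracles", {
  # 5-px-wide ribbon: interior skeleton calibers ~5 px
  m <- matrix(FALSE, 40, 120)
  m[18:22, 10:110] <- TRUE
  cal <- estimate_calibers(m)
  sk <- attr(cal, "skeleton")
  interior <- sk & col(m) > 30 & col(m) < 90
  expect_true(any(interior))
  expect_true(all(abs(cal[interior] - 5) <= 0.5))
  # 1-px line
  m1 <- matrix(FALSE, 20, 60); m1[10, 5:55] <- TRUE
  c1 <- estimate_calibers(m1)
  expect_true(all(c1[!is.na(c1)] >= 1 & c1[!is.na(c1)] <= 2))
  # disc of radius r: max caliber ~ 2r at the centre
  r <- 9
  g <- expand.grid(i = 1:41, j = 1:41)
  disc <- matrix((g$i - 21)^2 + (g$j - 21)^2 <= r^2, 41, 41)
  cd <- estimate_calibers(disc)
  expect_equal(max(cd, na.rm = TRUE), 2 * r, tolerance = 0.12)
  expect_error(estimate_calibers(matrix(FALSE, 5, 5)), "empty")
})

test_that("no congestion is detected in a dim uniform-caliber network", {
  case <- small_phantom_case()
  n <- 200
  img <- matrix(0, n, n)
  img[case$truth$dcp_vessels] <- 6000  # dim, 1-px-ish network only
  ang <- enface_angiogram(img, "DCP", 30)
  det <- detect_congestion(ang, case$truth$masks[["DCP-A"]],
                           case$truth$masks[["DCP-FAZ"]])
  expect_equal(sum(det), 0)
})

test_that("detector recovers the phantom congestion corridor", {
  case <- small_phantom_case()
  det <- detect_congestion(case$dcp, case$truth$masks[["DCP-A"]],
                           case$truth$masks[["DCP-FAZ"]])
  gt <- as.logical(case$truth$masks[["DCP-C"]])
  dd <- as.logical(det)
  expect_gte(sum(dd & gt) / sum(dd | gt), 0.8)
  # detected congestion never intersects the FAZ and stays near vessels
  expect_equal(sum(dd & as.logical(case$truth$masks[["DCP-FAZ"]])), 0)
  dil <- EBImage::imageData(EBImage::dilate(
    extract_vessels(case$dcp) * 1, matrix(1, 3, 3))) > 0
  expect_true(all(dil[dd]))
})

test_that("a corridor outside the boundary band is rejected", {
  cfg <- small_phantom_config(corridor_offset_px = 45)
  case <- generate_phantom_case(cfg)
  det0 <- detect_congestion(case$dcp, case$truth$masks[["DCP-A"]],
                            case$truth$masks[["DCP-FAZ"]],
                            congestion_params(boundary_band_px = 0))
  expect_equal(sum(det0), 0)
  det_wide <- detect_congestion(case$dcp, case$truth$masks[["DCP-A"]],
                                case$truth$masks[["DCP-FAZ"]],
                                congestion_params(boundary_band_px = 60))
  expect_gt(sum(det_wide), 0)
})

test_that("raising the brightness threshold never grows the detection", {
  case <- small_phantom_case()
  sizes <- vapply(c(20000, 32768, 48000, 60000), function(th) {
    sum(detect_congestion(case$dcp, case$truth$masks[["DCP-A"]],
                          case$truth$masks[["DCP-FAZ"]],
                          congestion_params(bright_threshold = th)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("masks survive the PNG round trip", {
  withr::with_seed(31, {
    m <- region_mask(random_mask(32), "DCP-C", 10)
    f <- withr::local_tempfile(fileext = ".png")
    save_mask(m, f)
    back <- load_mask(f, "DCP-C", 10)
    expect_equal(matrix(as.logical(back), 32, 32),
                 matrix(as.logical(m), 32, 32))
    # all-FALSE round trip
    z <- region_mask(matrix(FALSE, 8, 8), "TZ", 10)
    save_mask(z, f)
    expect_false(any(load_mask(f, "TZ")))
    # 8-bit {0,255} file reads TRUE exactly at 255
    raw <- matrix(c(0, 255, 255, 0), 2, 2)
    png::writePNG(raw / 255, f)
    got <- load_mask(f, "TZ")
    expect_equal(matrix(as.logical(got), 2, 2), raw == 255)
    expect_error(load_mask(f, "TZ", expect_dim = c(3, 3)), "expected")
  })
})
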