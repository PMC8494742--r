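test_that("identity pairs give the identity transform with zero residual", {
  withr::with_seed(51, {
    p <- matrix(runif(20, 10, 90), 10, 2)
    tfm <- fit_affine(control_points(p, p))
    expect_equal(tfm$matrix, diag(3), tolerance = 1e-12)
    expect_equal(tfm$rms_residual_px, 0, tolerance = 1e-12)
  })
})

test_that("a known affine is recovered exactly from noise-free points", {
  true <- affine_from_params(rotation_deg = 10, scale = 1.02,
                             tx = 5, ty = -3)
  src <- rbind(c(10, 10), c(90, 15), c(20, 80), c(70, 60))
  dst <- apply_affine(true, src)
  tfm <- fit_affine(control_points(src, dst))
  expect_lt(max(abs(tfm$matrix - true$matrix)), 1e-9)
  expect_lt(tfm$rms_residual_px, 1e-9)
})

test_that("residual under Gaussian jitter approximates the injected sigma", {
  withr::with_seed(52, {
    true <- affine_from_params(rotation_deg = 4, scale = 0.99, tx = 2, ty = 7)
    src <- cbind(runif(16, 5, 95), runif(16, 5, 95))
    dst <- apply_affine(true, src) + matrix(rnorm(32, 0, 0.5), 16, 2)
    tfm <- fit_affine(control_points(src, dst))
    expect_equal(tfm$rms_residual_px, 0.5, tolerance = 0.45)
  })
})

test_that("degenerate control points are rejected", {
  line <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(control_points(line, line), "collinear")
  expect_error(control_points(rbind(c(1, 1), c(2, 2)),
                              rbind(c(1, 1), c(2, 2))), "at least 3")
})

test_that("inverse and composition identities hold", {
  true <- affine_from_params(rotation_deg = -7, scale = 1.05, tx = -4, ty = 9)
  src <- rbind(c(10, 20), c(80, 15), c(30, 70), c(60, 55), c(45, 40))
  dst <- apply_affine(true, src)
  fwd <- fit_affine(control_points(src, dst))
  bwd <- fit_affine(control_points(dst, src))
  expect_lt(max(abs(bwd$matrix - solve(fwd$matrix))), 1e-6)
})

test_that("warping with the identity reproduces the map on a full overlap", {
  withr::with_seed(53, {
    m <- matrix(runif(40 * 40, 100, 300), 40, 40)
    w <- warp_map(m, affine_from_params())
    expect_true(all(w$overlap))
    expect_equal(as.matrix(w$map), m, ignore_attr = TRUE)
  })
})

test_that("integer translation shifts values exactly and trims the overlap", {
  withr::with_seed(54, {
    m <- matrix(runif(30 * 30, 0, 1), 30, 30)
    w <- warp_map(m, affine_from_params(tx = 10, ty = 0))
    expect_false(any(w$overlap[, 21:30]))
    expect_true(all(w$overlap[, 1:20]))
    expect_equal(as.matrix(w$map)[, 1:20], m[, 11:30], ignore_attr = TRUE)
  })
})

test_that("a constant field is invariant under any valid warp", {
  m <- matrix(250, 25, 25)
  w <- warp_map(m, affine_from_params(rotation_deg = 13, scale = 1.03,
                                      tx = 1.7, ty = -2.2,
                                      center = c(13, 13)))
  vals <- as.matrix(w$map)[w$overlap]
  expect_true(length(vals) > 0)
  expect_equal(max(abs(vals - 250)), 0, tolerance = 1e-9)
})

test_that("warp respects composition on a smooth field", {
  g <- expand.grid(x = 1:50, y = 1:50)
  smooth <- matrix(sin(g$x / 9) + cos(g$y / 7), 50, 50)
  A <- affine_from_params(tx = 2.3, ty = -1.1)
  B <- affine_from_params(rotation_deg = 3, center = c(25, 25))
  # with inverse mapping, warping by A then B samples m at A(B(y))
  BA <- structure(list(matrix = A$matrix %*% B$matrix, rms_residual_px = 0),
                  class = "affine2d")
  w1 <- warp_map(warp_map(smooth, A)$map, B)
  w2 <- warp_map(smooth, BA)
  both <- w1$overlap & w2$overlap &
    !is.na(as.matrix(w1$map)) & !is.na(as.matrix(w2$map))
  # interior only: double interpolation near edges differs more
  inner <- matrix(FALSE, 50, 50); inner[10:40, 10:40] <- TRUE
  both <- both & inner
  expect_true(any(both))
  expect_lt(max(abs(as.matrix(w1$map)[both] - as.matrix(w2$map)[both])), 0.02)
})

test_that("control points survive a CSV round trip", {
  withr::with_seed(55, {
    src <- cbind(runif(6, 1, 99), runif(6, 1, 99))
    dst <- src + 3
    cp <- control_points(src, dst)
    f <- withr::local_tempfile(fileext = ".csv")
    write_control_points(cp, f)
    back <- read_control_points(f)
    expect_equal(back$src, cp$src)
    expect_equal(back$dst, cp$dst)
  })
})
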