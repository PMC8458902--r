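loop_rmse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  sqrt(s / length(a))
}
loop_psnr <- function(a, b, mx = 1) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  10 * log10(mx^2 / (s / length(a)))
}

test_that("rmse matches hand values and the direct-loop oracle", {
  a <- matrix(runif(35 * 35), 35, 35)
  expect_identical(img_rmse(a, a), 0)
  expect_equal(img_rmse(a, a + 0.1), 0.1, tolerance = 1e-12)
  b <- matrix(runif(35 * 35), 35, 35)
  expect_lt(abs(img_rmse(a, b) - loop_rmse(a, b)), 1e-12)
  expect_error(img_rmse(a, matrix(0, 3, 3)), "shape")
})

test_that("psnr matches hand values, the loop oracle, and scale invariance", {
  a <- matrix(0.5, 30, 30)
  expect_equal(img_psnr(a, a + 0.1), 20, tolerance = 1e-12)   # MSE 0.01
  expect_equal(img_psnr(a, a + 0.01), 40, tolerance = 1e-12)  # MSE 1e-4
  set.seed(6)
  b <- matrix(runif(900), 30, 30)
  expect_lt(abs(img_psnr(a, b) - loop_psnr(a, b)), 1e-12)
  expect_equal(img_psnr(2 * a, 2 * b, max_val = 2), img_psnr(a, b),
               tolerance = 1e-12)
  expect_identical(img_psnr(b, b), Inf)
})

test_that("ssim: perfect value iff identical, constant-image closed form, symmetry", {
  set.seed(7)
  a <- matrix(runif(40 * 40), 40, 40)
  expect_identical(img_ssim(a, a)$mean, 1)
  b <- a + matrix(rnorm(1600, sd = 0.05), 40, 40)
  expect_lt(img_ssim(a, b)$mean, 1)
  expect_equal(img_ssim(a, b)$mean, img_ssim(b, a)$mean, tolerance = 1e-12)

  c1 <- 0.01^2
  closed <- (2 * 0.5 * 0.25 + c1) / (0.5^2 + 0.25^2 + c1)
  got <- img_ssim(matrix(0.5, 32, 32), matrix(0.25, 32, 32))$mean
  expect_equal(got, closed, tolerance = 1e-6)
  expect_equal(got, 0.8001, tolerance = 1e-4)   # closed form = 0.800064
  expect_error(img_ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("fsim: identity, symmetry, flat-pair conventions, shift invariance", {
  ph <- make_phantom(phantom_spec(), seed = 44L)
  a <- normalize_intensity(fit_adc(ph$clean_dwi)$data)
  expect_identical(img_fsim(a, a), 1)
  set.seed(8)
  b <- pmin(pmax(a + matrix(rnorm(length(a), sd = 0.05), nrow(a)), 0), 1)
  expect_equal(img_fsim(a, b), img_fsim(b, a), tolerance = 1e-12)
  expect_identical(img_fsim(matrix(3, 32, 32), matrix(3, 32, 32)), 1)
  expect_error(img_fsim(matrix(3, 32, 32), a[1:32, 1:32]), "flat")
  expect_equal(img_fsim(a + 0.3, b + 0.3), img_fsim(a, b), tolerance = 1e-12)
})

test_that("fsim decreases strictly along a noise ladder", {
  ph <- make_phantom(phantom_spec(), seed = 45L)
  a <- normalize_intensity(fit_adc(ph$clean_dwi)$data)
  vals <- vapply(c(0.01, 0.05, 0.1), function(sig) {
    noisy <- a + adcgan:::with_seed(99L, matrix(rnorm(length(a), sd = sig), nrow(a)))
    img_fsim(a, noisy)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals < 1))
})

test_that("diameter distortion follows mask geometry exactly", {
  m <- matrix(FALSE, 30, 30); m[10:20, 8:22] <- TRUE
  d0 <- diameter_distortion(m, m, c(0.95, 0.95))
  expect_identical(c(d0$delta_ap, d0$delta_lr), c(0, 0))

  dil <- m; dil[9, 8:22] <- TRUE; dil[21, 8:22] <- TRUE
  d1 <- diameter_distortion(dil, m, c(0.95, 0.95))
  expect_equal(d1$delta_ap, 1.9, tolerance = 1e-12)
  expect_identical(d1$delta_lr, 0)
  expect_error(diameter_distortion(matrix(FALSE, 3, 3), m), "empty")
})

test_that("degraded-arm prostate masks show larger AP distortion than clean", {
  sp <- phantom_spec(max_displacement_px = 4)
  f_ap <- z_ap <- numeric(4)
  for (i in 1:4) {
    ph <- make_phantom(sp, seed = 300L + i)
    z <- mask_from_adc(fit_adc(ph$clean_dwi))
    f <- mask_from_adc(fit_adc(ph$degraded_dwi))
    z_ap[i] <- diameter_distortion(z, ph$masks$prostate, sp$voxel_spacing)$delta_ap
    f_ap[i] <- diameter_distortion(f, ph$masks$prostate, sp$voxel_spacing)$delta_ap
  }
  expect_gt(mean(f_ap), mean(z_ap))
})
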