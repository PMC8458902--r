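test_that("tissue ADC levels are reproduced exactly when variability is off", {
  sp <- fixture_spec(zone_adc_sds = c(pz = 0, tz = 0, benign = 0, malignant = 0),
                     texture_amp = 0)
  ph <- make_phantom(sp, seed = 3L)
  expect_true(all(abs(ph$true_adc$data[ph$masks$pz] - 1.43e-3) < 1e-15))
  expect_true(all(abs(ph$true_adc$data[ph$masks$tz] - 1.20e-3) < 1e-15))
  expect_true(all(abs(ph$true_adc$data[ph$masks$lesion] - 0.61e-3) < 1e-15))
})

test_that("identical (spec, seed) gives a bit-identical case", {
  sp <- fixture_spec()
  expect_identical(make_phantom(sp, seed = 17L), make_phantom(sp, seed = 17L))
  expect_false(identical(make_phantom(sp, seed = 17L),
                         make_phantom(sp, seed = 18L)))
})

test_that("lesion ADC draws follow the specified normal law (Monte-Carlo)", {
  sp <- fixture_spec(lesion_class = "malignant", texture_amp = 0)
  n <- 200L
  means <- vapply(seq_len(n), function(i) {
    ph <- make_phantom(sp, seed = 1000L + i)
    mean(ph$true_adc$data[ph$masks$lesion])
  }, numeric(1))
  se <- 0.11e-3 / sqrt(n)
  expect_lt(abs(mean(means) - 0.61e-3), 3 * se)
})

test_that("an oversized lesion is rejected with a geometry error", {
  expect_error(make_phantom(fixture_spec(lesion_radius_mm = 20), seed = 1L),
               "geometry")
})

test_that("mask invariants hold", {
  ph <- make_phantom(fixture_spec(), seed = 9L)
  expect_false(any(ph$masks$pz & ph$masks$tz))
  expect_true(all(ph$masks$lesion[ph$masks$lesion] &
                  ph$masks$prostate[ph$masks$lesion]))
  expect_identical(ph$clean_dwi$b_values, ph$degraded_dwi$b_values)
  expect_true(all(ph$true_adc$data[ph$masks$prostate] > 0))
})

test_that("DWI simulation follows mono-exponential decay exactly at zero noise", {
  adc <- matrix(1.0e-3, 4, 4)
  s0 <- matrix(1, 4, 4)
  dwi <- simulate_dwi(adc, s0, b_values = c(0, 1000), noise_sigma = 0)
  expect_equal(dwi$data[2, 1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(dwi$data[1, , ], s0, tolerance = 0)
  expect_error(simulate_dwi(adc, s0, b_values = c(-10, 100)), "negative b")
})

test_that("pure-noise magnitude matches the Rayleigh closed-form mean", {
  n <- 320L
  adc <- matrix(1e-3, n, n)      # irrelevant: s0 = 0
  s0 <- matrix(0, n, n)
  sig <- 0.1
  dwi <- simulate_dwi(adc, s0, b_values = c(50), noise_sigma = sig,
                      seed = 4L, s0_level = 1)
  expect_lt(abs(mean(dwi$data) / (sig * sqrt(pi / 2)) - 1), 0.01)
})

test_that("identity degradation is bit-identical and conserves structure", {
  sp <- fixture_spec(max_displacement_px = 0, blur_sigma_px = 0,
                     downsample_factor = 1, noise_sigma_degraded = 0)
  ph <- make_phantom(sp, seed = 2L)
  dwi <- ph$clean_dwi
  out <- degrade_to_ffov(dwi, sp, seed = 11L)
  expect_identical(out$data, dwi$data)
  expect_identical(out$b_values, dwi$b_values)
  expect_identical(dim(out$data), dim(dwi$data))
})

test_that("displacement field peak never exceeds the configured maximum", {
  sp <- fixture_spec(max_displacement_px = 4)
  for (seed in c(1L, 12L, 123L)) {
    ph <- make_phantom(sp, seed = seed)
    expect_lte(max(abs(ph$degraded_dwi$displacement)), 4 + 1e-6)
  }
})

test_that("distortion is anterior-posterior only: LR diameter is preserved", {
  ph <- make_phantom(fixture_spec(max_displacement_px = 4), seed = 21L)
  d <- diameter_distortion(ph$masks_degraded$prostate, ph$masks$prostate,
                           ph$spec$voxel_spacing)
  expect_gt(d$delta_ap, 0)
  expect_lte(d$delta_lr, ph$spec$voxel_spacing[2] + 1e-9)
})

test_that("batch generation yields the exact requested label counts", {
  cohort <- make_cohort(3L, 4L, 2L, fixture_spec(), seed = 6L)
  labs <- vapply(cohort, `[[`, "", "label")
  expect_identical(sum(labs == "benign"), 3L)
  expect_identical(sum(labs == "malignant"), 4L)
  expect_identical(sum(labs == "none"), 2L)
})

test_that("ROI radius follows circle-area geometry", {
  roi <- reader_roi(center = c(16, 16), radius_px = sqrt(50 / pi) / 0.95,
                    spacing = c(0.95, 0.95))
  expect_equal(roi$area_cm2, 0.5, tolerance = 1e-12)
  expect_equal(roi$radius_px, 4.199, tolerance = 1e-3)
})

test_that("ROI placement is deterministic without jitter and errors on small masks", {
  mask <- disc_mask <- matrix(FALSE, 40, 40)
  mask[(row(mask) - 20)^2 + (col(mask) - 20)^2 <= 100] <- TRUE
  r1 <- simulate_reader_rois(mask, c(0.95, 0.95), c(0.5, 0.8), jitter_px = 0,
                             reader_id = 1L, repetition = 1L, seed = 1L)
  r2 <- simulate_reader_rois(mask, c(0.95, 0.95), c(0.5, 0.8), jitter_px = 0,
                             reader_id = 1L, repetition = 2L, seed = 99L)
  expect_identical(r1$center, r2$center)
  expect_identical(r1$radius_px, r2$radius_px)
  tiny <- matrix(FALSE, 20, 20); tiny[9:11, 9:11] <- TRUE
  expect_error(simulate_reader_rois(tiny, c(0.95, 0.95), c(0.5, 0.8)),
               "minimum")
})

test_that("small jitter keeps inter-reader agreement of ROI means high", {
  sp <- fixture_spec()
  vals <- matrix(NA_real_, 40, 2)
  for (i in 1:40) {
    ph <- make_phantom(sp, seed = 5000L + i)
    for (rd in 1:2) {
      roi <- simulate_reader_rois(ph$masks$lesion, sp$voxel_spacing,
                                  c(0.3, 0.45), jitter_px = 1, reader_id = rd,
                                  repetition = 1L, seed = 31L * i + rd)
      vals[i, rd] <- roi_mean(ph$true_adc, roi)
    }
  }
  expect_gt(icc(vals, "two_way_random_absolute")$estimate, 0.9)
})
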