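test_that("classifier pre-training separates well-separated lesion classes", {
  # tight per-case SDs: the benign (0.98) vs malignant (0.61) lesion ADC gap
  # is then cleanly separated and a small classifier should recover it
  sp <- phantom_spec(zone_adc_sds = c(pz = 0.05e-3, tz = 0.05e-3,
                                      benign = 0.03e-3, malignant = 0.03e-3))
  cases <- make_cohort(20L, 20L, 0L, sp, seed = 70L)
  ys <- lapply(cases, function(c) pmin(pmax(fit_adc(c$clean_dwi)$data / 4e-3, 0), 1))
  labs <- vapply(cases, `[[`, "", "label")
  cfg <- train_config(epochs = 16L, batch_size = 5L, seed = 2L, image_size = 64L)
  cl <- pretrain_classifier(ys, labs, recognition_spec(base_width = 8L), cfg)
  expect_gte(cl$accuracy, 0.9)

  shuf <- adcgan:::with_seed(1L, sample(labs))
  cl0 <- pretrain_classifier(ys, shuf, recognition_spec(base_width = 8L), cfg)
  expect_lt(abs(cl0$accuracy - 0.5), 0.35)

  expect_error(pretrain_classifier(ys, rep("benign", length(ys)),
                                   recognition_spec(base_width = 8L), cfg),
               "2 classes")
})

test_that("classifier training is seed-deterministic", {
  x <- lapply(1:8, function(i) adcgan:::with_seed(i, matrix(runif(256), 16, 16)))
  labs <- rep(c("a", "b"), 4)
  cfg <- train_config(epochs = 2L, batch_size = 4L, seed = 3L, image_size = 16L)
  c1 <- pretrain_classifier(x, labs, recognition_spec(base_width = 2L), cfg)
  c2 <- pretrain_classifier(x, labs, recognition_spec(base_width = 2L), cfg)
  expect_identical(adcgan:::net_params(c1$model$trunk),
                   adcgan:::net_params(c2$model$trunk))
  expect_identical(c1$accuracy, c2$accuracy)
})

test_that("GAN training records a valid theta trajectory and loss history", {
  run <- tiny_gan_run()
  st <- run$state
  expect_equal(unname(st$theta_history[1, ]), rep(0.25, 4), tolerance = 1e-15)
  expect_true(all(abs(rowSums(st$theta_history) - 1) < 1e-9))
  # theta at epoch j+1 is ordered like the mean per-level losses of epoch j
  for (ep in seq_len(nrow(st$theta_history) - 1)) {
    lev <- as.numeric(st$history[ep, paste0("level_", c(0, 1, 3, 5))])
    expect_identical(order(st$theta_history[ep + 1, ]), order(lev))
  }
  expect_true(all(is.finite(as.matrix(st$history[, -1]))))
})

test_that("GAN training is deterministic and supports both ablations", {
  run <- tiny_gan_run()
  st2 <- train_gan(run$xs, run$ys, run$recog,
                   gen_spec = generator_spec(base_width = 4L,
                                             n_residual_blocks = 2L),
                   disc_spec = discriminator_spec(base_width = 4L),
                   config = train_config(epochs = 3L, batch_size = 3L,
                                         seed = 5L, image_size = 32L))
  expect_identical(run$state$history, st2$history)

  cfg1 <- train_config(epochs = 1L, batch_size = 3L, seed = 5L,
                       image_size = 32L, lambda1 = 0)
  st_l0 <- train_gan(run$xs, run$ys, run$recog, config = cfg1,
                     gen_spec = generator_spec(base_width = 4L,
                                               n_residual_blocks = 1L),
                     disc_spec = discriminator_spec(base_width = 4L))
  expect_true(is.finite(st_l0$history$loss_g[1]))

  cfg2 <- train_config(epochs = 1L, batch_size = 3L, seed = 5L, image_size = 32L)
  st_pix <- train_gan(run$xs, run$ys, recognizer = NULL, config = cfg2,
                      gen_spec = generator_spec(base_width = 4L,
                                                n_residual_blocks = 1L),
                      disc_spec = discriminator_spec(base_width = 4L))
  expect_identical(colnames(st_pix$theta_history), "0")
})

test_that("synthesis is deterministic, shape-preserving, and validates size", {
  run <- tiny_gan_run()
  s1 <- synthesize(run$state, run$xs[[1]])
  s2 <- synthesize(run$state, run$xs[[1]])
  expect_identical(s1$norm, s2$norm)
  expect_identical(dim(s1$norm), dim(run$xs[[1]]))
  expect_s3_class(s1$adc, "adc_map")
  expect_identical(s1$adc$provenance, "synthesized")
  expect_true(all(s1$adc$data >= 0 & s1$adc$data <= 4e-3))
  expect_error(synthesize(run$state, matrix(0.5, 16, 16)), "trained at")
})
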