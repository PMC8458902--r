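test_that("least-squares adversarial losses reproduce hand-computed values", {
  ones <- rep(1, 10); zeros <- rep(0, 10); half <- rep(0.5, 10)
  expect_equal(discriminator_loss(ones, zeros), 0, tolerance = 1e-15)
  expect_equal(discriminator_loss(zeros, ones), 2, tolerance = 1e-15)
  expect_equal(discriminator_loss(half, half), 0.5, tolerance = 1e-15)
  expect_equal(generator_adv_loss(ones), 0, tolerance = 1e-15)
  expect_equal(generator_adv_loss(zeros), 1, tolerance = 1e-15)
  expect_equal(generator_adv_loss(half), 0.25, tolerance = 1e-15)
  expect_error(discriminator_loss(numeric(0), ones), "empty")
  expect_error(generator_adv_loss(c(1, NaN)), "finite")
})

test_that("generator objective composes adversarial and MLV terms linearly", {
  cfg <- train_config(lambda1 = 0.1)
  expect_identical(generator_total_loss(1.0, 10.0, cfg), 2.0)
  expect_identical(generator_total_loss(0.73, 0, cfg), 0.73)
  cfg0 <- train_config(lambda1 = 0)
  expect_identical(generator_total_loss(0.42, 99, cfg0), 0.42)
  set.seed(5)
  for (i in 1:20) {
    adv <- runif(1, 0, 3); mlv <- runif(1, 0, 3)
    expect_equal(generator_total_loss(adv, mlv, cfg), adv + 0.1 * mlv,
                 tolerance = 1e-15)
  }
})

test_that("MLV loss matches its definition on constructed features", {
  f1 <- list(`0` = matrix(0, 4, 4), `1` = array(1, c(2, 2, 2, 1)),
             `3` = array(2, c(2, 2)), `5` = array(3, c(2, 2)))
  expect_identical(mlv_loss(f1, f1, theta_weights())$loss, 0)
  expect_identical(mlv_loss(f1, f1, theta_weights(), "mean")$loss, 0)

  fa <- list(`0` = matrix(0, 4, 4)); fb <- list(`0` = matrix(1, 4, 4))
  th0 <- theta_weights(c(1, 0, 0, 0))
  fa[c("1", "3", "5")] <- fb[c("1", "3", "5")] <- list(matrix(9, 2, 2))
  expect_identical(mlv_loss(fb, fa, th0, "mean")$loss, 1)   # MSE of offset 1
  expect_identical(mlv_loss(fb, fa, th0, "sum")$loss, 16)   # ||diff||^2, 4x4

  # theta (0.5, 0.5, 0, 0) with per-level losses (1, 3, 9.9, 9.9) -> 2.0
  mk <- function(v) matrix(sqrt(v), 1, 1)
  fs <- list(`0` = mk(1), `1` = mk(3), `3` = mk(9.9), `5` = mk(9.9))
  fz <- list(`0` = mk(0) * 0, `1` = mk(0) * 0, `3` = mk(0) * 0, `5` = mk(0) * 0)
  r <- mlv_loss(fs, fz, theta_weights(c(0.5, 0.5, 0, 0)), "mean")
  expect_equal(r$loss, 2.0, tolerance = 1e-12)
  expect_equal(unname(r$per_level), c(1, 3, 9.9, 9.9), tolerance = 1e-12)
  # batched squared-norm reduction averages over the batch only
  a4 <- array(1, c(2, 2, 1, 2)); b4 <- array(0, c(2, 2, 1, 2))
  expect_identical(mlv_loss(list(`0` = a4), list(`0` = b4),
                            theta_weights(1, levels = 0L))$loss, 4)
  expect_error(mlv_loss(list(`0` = matrix(0, 2, 2)),
                        list(`0` = matrix(0, 3, 3)),
                        theta_weights(1, levels = 0L)), "shape")
})

test_that("theta update is proportional normalization with the 1/4 fixed point", {
  for (c_ in c(0, 0.3, 7)) {
    th <- update_theta(rep(c_, 4))
    expect_equal(unname(unclass(th)), rep(0.25, 4), tolerance = 1e-12)
  }
  th <- update_theta(c(2, 1, 1, 0), epsilon = 1e-15)
  expect_equal(unname(unclass(th)), c(0.5, 0.25, 0.25, 0), tolerance = 1e-12)
  th0 <- update_theta(c(0, 0, 0, 0), epsilon = 1e-8)
  expect_equal(unname(unclass(th0)), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(sum(unclass(th)), 1, tolerance = 1e-9)
  expect_error(update_theta(c(-1, 0, 0, 0)), "negative")
  expect_error(theta_weights(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("feature extraction: identity level, shrinking maps, determinism", {
  recog <- build_recognizer(recognition_spec(base_width = 4L),
                            image_size = 32L, seed = 3L)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  f <- extract_features(recog, x)$features
  expect_identical(f[["0"]], x)
  sizes <- vapply(c("1", "3", "5"), function(l) dim(f[[l]])[1], numeric(1))
  expect_true(all(diff(sizes) <= 0))
  f2 <- extract_features(recog, x)$features
  expect_identical(f, f2)
})
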