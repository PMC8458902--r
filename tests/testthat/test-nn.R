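# Finite-difference gradient checks anchor the hand-written backpropagation.

test_that("convolution forward/backward matches numerical gradients", {
  set.seed(1)
  for (stride in c(1L, 2L)) {
    x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
    w <- array(rnorm(3 * 3 * 2 * 3, sd = 0.5), c(3, 3, 2, 3))
    b <- rnorm(3)
    y <- adcgan:::.nn_conv_fwd(x, w, b, stride, 1L)
    proj <- array(rnorm(length(y)), dim(y))
    g <- adcgan:::.nn_conv_bwd(x, w, proj, stride, 1L, TRUE)
    fx <- function(xx) sum(adcgan:::.nn_conv_fwd(xx, w, b, stride, 1L) * proj)
    fw <- function(ww) sum(adcgan:::.nn_conv_fwd(x, ww, b, stride, 1L) * proj)
    fb <- function(bb) sum(adcgan:::.nn_conv_fwd(x, w, bb, stride, 1L) * proj)
    idx <- sample(length(x), 12)
    expect_lt(max(abs(num_grad(fx, x, idx) - g$gx[idx])), 1e-6)
    idxw <- sample(length(w), 12)
    expect_lt(max(abs(num_grad(fw, w, idxw) - g$gw[idxw])), 1e-6)
    expect_lt(max(abs(num_grad(fb, b, 1:3) - g$gb)), 1e-6)
  }
})

test_that("generator backpropagation matches numerical gradients", {
  set.seed(2)
  gen <- build_generator(generator_spec(base_width = 2L, n_residual_blocks = 1L,
                                        n_down = 2L), seed = 4L)
  x <- array(runif(8 * 8), c(8, 8, 1, 1))
  proj <- array(rnorm(64), c(8, 8, 1, 1))
  loss <- function(net) {
    g2 <- gen; g2$net <- net
    sum(adcgan:::gen_forward(g2, x, keep = FALSE)$out * proj)
  }
  fwd <- adcgan:::gen_forward(gen, x, keep = TRUE)
  bk <- adcgan:::net_backward(gen$net, fwd, proj, need_gx = FALSE)
  for (li in c(1L, 7L, length(gen$net) - 1L)) {   # conv, resblock, last conv
    pn <- names(gen$net[[li]]$params)[1]
    ga <- bk$grads[[li]][[pn]]
    idx <- seq_len(min(5, length(ga)))
    gn <- vapply(idx, function(i) {
      np <- gen$net; np[[li]]$params[[pn]][i] <- np[[li]]$params[[pn]][i] + 1e-5
      nm <- gen$net; nm[[li]]$params[[pn]][i] <- nm[[li]]$params[[pn]][i] - 1e-5
      (loss(np) - loss(nm)) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(gn - ga[idx])), 1e-5)
  }
})

test_that("discriminator input gradients match numerical gradients", {
  set.seed(3)
  disc <- build_discriminator(discriminator_spec(base_width = 2L), seed = 5L)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  fwd <- adcgan:::disc_forward(disc, x, keep = TRUE)
  gy <- 2 * (fwd$out - 1) / length(fwd$out)
  gx <- adcgan:::net_backward(disc$net, fwd, gy, need_gx = TRUE)$gx
  f <- function(xx) {
    o <- adcgan:::disc_forward(disc, xx, keep = FALSE)$out
    mean((o - 1)^2)
  }
  idx <- sample(length(x), 10)
  expect_lt(max(abs(num_grad(f, x, idx) - gx[idx])), 1e-6)
})

test_that("multi-level feature loss gradient w.r.t. the image is exact", {
  set.seed(4)
  recog <- build_recognizer(recognition_spec(base_width = 2L),
                            image_size = 16L, seed = 6L)
  s <- array(runif(16 * 16), c(16, 16, 1, 1))
  y <- array(runif(16 * 16), c(16, 16, 1, 1))
  theta <- theta_weights(c(0.4, 0.3, 0.2, 0.1))
  mg <- adcgan:::mlv_grad_wrt_s(recog, s, y, theta, scale = 1)
  f <- function(ss) {
    fs <- extract_features(recog, ss)$features
    fy <- extract_features(recog, y)$features
    mlv_loss(fs, fy, theta)$loss
  }
  idx <- sample(length(s), 10)
  expect_lt(max(abs(num_grad(f, s, idx) - mg$grad[idx])), 1e-6)
})

test_that("generator preserves spatial shape and validates divisibility", {
  gen <- build_generator(generator_spec(base_width = 4L), seed = 1L)
  for (n in c(32L, 64L)) {
    x <- array(runif(n * n), c(n, n, 1, 1))
    expect_identical(dim(adcgan:::gen_forward(gen, x, keep = FALSE)$out),
                     c(n, n, 1L, 1L))
  }
  bad <- array(runif(30 * 30), c(30, 30, 1, 1))
  expect_error(adcgan:::gen_forward(gen, bad), "divisible")
})

test_that("seeded builders are deterministic", {
  expect_identical(adcgan:::net_params(build_generator(seed = 9L)$net),
                   adcgan:::net_params(build_generator(seed = 9L)$net))
  expect_identical(adcgan:::net_params(build_discriminator(seed = 9L)$net),
                   adcgan:::net_params(build_discriminator(seed = 9L)$net))
})
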