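# Training: classifier pre-training, adversarial training with the
# multi-level verification loss, and inference.
#
# Per batch the discriminator is updated on L_D, then the generator on
# L_G = L_G^adv + lambda1 * L_G^mlv with the recognition model frozen.
# The level weights theta start at 1/4 each and are re-normalized once per
# epoch in proportion to the previous epoch's mean per-level losses. All
# randomness flows through the config seed, so two runs with the same seed
# and device produce identical loss histories.

#' Training configuration
#'
#' @param learning_rate Adam step size (both networks).
#' @param batch_size slices per batch.
#' @param epochs training epochs.
#' @param lambda1 weight of the multi-level verification loss in the
#'   generator objective.
#' @param seed master seed for initialization, shuffling, and splits.
#' @param image_size trained square resolution in pixels.
#' @param feature_levels levels of the multi-level verification loss.
#' @param theta_epsilon guard for the theta renormalization.
#' @param mlv_reduction per-level feature-loss reduction (see [mlv_loss()]).
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 5L, epochs = 50L,
                         lambda1 = 0.1, seed = 1L, image_size = 224L,
                         feature_levels = c(0L, 1L, 3L, 5L),
                         theta_epsilon = 1e-8,
                         mlv_reduction = c("sum", "mean")) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1, lambda1 >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lambda1 = lambda1,
                 seed = as.integer(seed), image_size = as.integer(image_size),
                 feature_levels = as.integer(feature_levels),
                 theta_epsilon = theta_epsilon,
                 mlv_reduction = match.arg(mlv_reduction)),
            class = "train_config")
}

stack_tensor <- function(slices) {
  d <- dim(as.matrix(slices[[1]]))
  x <- array(0, dim = c(d[1], d[2], 1L, length(slices)))
  for (i in seq_along(slices)) x[, , 1L, i] <- as.matrix(slices[[i]])
  x
}

#' Pre-train the recognition (benign/malignant) classifier
#'
#' Cross-entropy training of the VGG-style recognition model on labelled,
#' normalized slices; returns the frozen model plus held-out accuracy.
#'
#' @param slices list of normalized image matrices.
#' @param labels character/factor labels (exactly 2 classes required).
#' @param spec a [recognition_spec()].
#' @param config a [train_config()] (its `epochs`, `batch_size`,
#'   `learning_rate`, `seed` are used).
#' @param holdout_frac fraction of slices held out for the accuracy estimate.
#' @export
pretrain_classifier <- function(slices, labels, spec = recognition_spec(),
                                config = train_config(), holdout_frac = 0.25) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("exactly 2 classes required")
  y <- as.integer(labels)
  n <- length(slices)
  seeds <- child_seeds(config$seed, 2 + config$epochs)
  model <- build_recognizer(spec, image_size = nrow(as.matrix(slices[[1]])),
                            seed = seeds[1])
  idx <- with_seed(seeds[2], sample.int(n))
  n_hold <- max(1L, round(holdout_frac * n))
  hold <- idx[seq_len(n_hold)]
  train <- idx[-seq_len(n_hold)]
  if (length(unique(y[train])) < 2L) stop("training split lost a class")

  params <- list(trunk = net_params(model$trunk), head = net_params(model$head))
  opt <- adam_init(params)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(seeds[2 + ep], sample(train))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      x <- stack_tensor(slices[bt])
      fw <- recog_forward(model, x, keep = TRUE)
      ce <- softmax_ce(fw$logits, y[bt])
      bh <- net_backward(model$head, fw$head, ce$grad, need_gx = TRUE)
      btr <- net_backward(model$trunk, fw$trunk, bh$gx, need_gx = FALSE)
      grads <- list(trunk = btr$grads, head = bh$grads)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
      model$trunk <- net_set_params(model$trunk, params$trunk)
      model$head <- net_set_params(model$head, params$head)
      ep_loss <- ep_loss + ce$loss * length(bt)
    }
    history[ep] <- ep_loss / length(train)
  }
  xh <- stack_tensor(slices[hold])
  pred <- apply(recog_forward(model, xh, keep = FALSE)$logits, 2, which.max)
  acc <- mean(pred == y[hold])
  list(model = model, accuracy = acc, history = history,
       classes = levels(labels), holdout = hold)
}

# Gradient of the MLV loss with respect to S (through the frozen classifier).
mlv_grad_wrt_s <- function(model, s, y, theta, scale = 1, reduction = "sum") {
  fs <- extract_features(model, s, keep = TRUE)
  fy <- extract_features(model, y, keep = FALSE)
  ml <- mlv_loss(fs$features, fy$features, theta, reduction = reduction)
  lev <- names(theta)
  inject <- list()
  g0 <- NULL
  for (l in lev) {
    w <- scale * unclass(theta)[[l]]
    if (w == 0) next
    f <- fs$features[[l]]
    denom <- if (reduction == "sum") {
      if (length(dim(f)) == 4L) dim(f)[4] else 1L
    } else length(f)
    diffg <- 2 * (f - fy$features[[l]]) / denom
    if (l == "0") g0 <- w * diffg
    else inject[[as.character(model$taps[[l]])]] <- w * diffg
  }
  gs <- if (length(inject))
    net_backward(model$trunk, fs$trunk, gy = NULL, inject = inject,
                 need_gx = TRUE)$gx
  else 0
  if (!is.null(g0)) gs <- gs + g0
  list(grad = gs, loss = ml$loss, per_level = ml$per_level)
}

#' Train the ADC-synthesis GAN
#'
#' @param x_slices list of normalized input slices (single-b-value full-FOV
#'   DWI) at the training resolution.
#' @param y_slices list of paired normalized reference slices (zoomed-FOV ADC).
#' @param recognizer frozen recognition model for the multi-level loss
#'   (`NULL` restricts the levels to level 0, i.e. pixel supervision only).
#' @param gen_spec,disc_spec architecture specifications.
#' @param config a [train_config()].
#' @param norm list(lo, hi): the linear mm^2/s range mapped onto [0, 1] in the
#'   references, stored for de-normalizing synthesized maps.
#' @param verbose print per-epoch losses.
#' @return a `train_state`: trained networks, theta trajectory, loss history,
#'   and the initial generator (for progress baselines).
#' @export
train_gan <- function(x_slices, y_slices, recognizer,
                      gen_spec = generator_spec(), disc_spec = discriminator_spec(),
                      config = train_config(), norm = list(lo = 0, hi = 4e-3),
                      verbose = FALSE) {
  n <- length(x_slices)
  stopifnot(n >= 1, length(y_slices) == n)
  levels <- config$feature_levels
  if (is.null(recognizer)) levels <- 0L
  seeds <- child_seeds(config$seed, 2 + config$epochs)
  gen <- build_generator(gen_spec, seed = seeds[1])
  disc <- build_discriminator(disc_spec, seed = seeds[2])
  gen_init <- gen

  gp <- net_params(gen$net); dp <- net_params(disc$net)
  gopt <- adam_init(gp); dopt <- adam_init(dp)
  theta <- theta_weights(rep(1 / length(levels), length(levels)), levels = levels)

  hist <- vector("list", config$epochs)
  theta_hist <- matrix(NA_real_, config$epochs, length(levels),
                       dimnames = list(NULL, names(theta)))

  for (ep in seq_len(config$epochs)) {
    theta_hist[ep, ] <- unclass(theta)
    ord <- with_seed(seeds[2 + ep], sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    acc <- c(loss_d = 0, loss_g_adv = 0, loss_g_mlv = 0, loss_g = 0)
    lev_acc <- setNames(numeric(length(levels)), names(theta))
    nb <- 0L
    for (bt in batches) {
      x <- stack_tensor(x_slices[bt])
      y <- stack_tensor(y_slices[bt])
      gf <- gen_forward(gen, x, keep = TRUE)
      s <- gf$out

      # --- discriminator step ---
      fr <- disc_forward(disc, y, keep = TRUE)
      ff <- disc_forward(disc, s, keep = TRUE)
      l_d <- discriminator_loss(fr$out, ff$out)
      m <- length(fr$out)
      br <- net_backward(disc$net, fr, 2 * (fr$out - 1) / m, need_gx = FALSE)
      bf <- net_backward(disc$net, ff, 2 * ff$out / m, need_gx = FALSE)
      dgrads <- map2_rec(br$grads, bf$grads, `+`)
      st <- adam_step(dp, dgrads, dopt, config$learning_rate)
      dp <- st$params; dopt <- st$state
      disc$net <- net_set_params(disc$net, dp)

      # --- generator step ---
      ff2 <- disc_forward(disc, s, keep = TRUE)
      l_adv <- generator_adv_loss(ff2$out)
      g_s <- net_backward(disc$net, ff2, 2 * (ff2$out - 1) / length(ff2$out),
                          need_gx = TRUE)$gx
      if (!is.null(recognizer)) {
        mg <- mlv_grad_wrt_s(recognizer, s, y, theta, scale = config$lambda1,
                             reduction = config$mlv_reduction)
      } else {
        nb <- if (config$mlv_reduction == "sum") dim(s)[4] else length(s)
        per <- c(`0` = sum((s - y)^2) / nb)
        mg <- list(grad = config$lambda1 * unclass(theta)[["0"]] *
                     2 * (s - y) / nb,
                   loss = unname(per), per_level = per)
      }
      l_mlv <- mg$loss
      l_g <- generator_total_loss(l_adv, l_mlv, config)
      if (!is.finite(l_d) || !is.finite(l_g))
        stop(sprintf("non-finite loss at epoch %d (L_D = %g, L_G^adv = %g, L_G^mlv = %g)",
                     ep, l_d, l_adv, l_mlv))
      bg <- net_backward(gen$net, gf, g_s + mg$grad, need_gx = FALSE)
      st <- adam_step(gp, bg$grads, gopt, config$learning_rate)
      gp <- st$params; gopt <- st$state
      gen$net <- net_set_params(gen$net, gp)

      acc <- acc + c(l_d, l_adv, l_mlv, l_g)
      lev_acc <- lev_acc + mg$per_level[names(lev_acc)]
      nb <- nb + 1L
    }
    acc <- acc / nb
    lev_mean <- lev_acc / nb
    hist[[ep]] <- c(epoch = ep, acc, setNames(lev_mean, paste0("level_", names(lev_mean))),
                    setNames(unclass(theta), paste0("theta_", names(theta))))
    if (verbose)
      message(sprintf("epoch %d: L_D %.4f  L_G^adv %.4f  L_G^mlv %.5f",
                      ep, acc[["loss_d"]], acc[["loss_g_adv"]], acc[["loss_g_mlv"]]))
    theta <- update_theta(lev_mean, epsilon = config$theta_epsilon,
                          levels = levels)
  }
  history <- as.data.frame(do.call(rbind, hist))
  structure(list(generator = gen, discriminator = disc,
                 generator_init = gen_init, theta = theta,
                 theta_history = theta_hist, history = history,
                 config = config, norm = norm),
            class = "train_state")
}

#' Synthesize an ADC map from a single-b-value DWI slice
#'
#' @param state a `train_state` from [train_gan()] (or a bare
#'   `adcgan_generator` plus `norm`).
#' @param slice normalized input matrix at the trained resolution.
#' @param generator override generator (e.g. `state$generator_init`).
#' @return list with `norm` (the [0, 1] output) and `adc` (an [adc_map()]
#'   in mm^2/s, provenance `synthesized`).
#' @export
synthesize <- function(state, slice, generator = NULL) {
  gen <- if (!is.null(generator)) generator else state$generator
  x <- as.matrix(slice)
  if (!is.null(state$config) &&
      !all(dim(x) == state$config$image_size))
    stop(sprintf("slice is %dx%d but the model was trained at %dx%d",
                 nrow(x), ncol(x), state$config$image_size,
                 state$config$image_size))
  out <- gen_forward(gen, x, keep = FALSE)$out[, , 1L, 1L]
  lo <- state$norm$lo; hi <- state$norm$hi
  adc <- pmin(pmax(lo + out * (hi - lo), lo), hi)
  list(norm = out,
       adc = adc_map(adc, provenance = "synthesized", clip_range = c(lo, hi)))
}
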