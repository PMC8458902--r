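# Adversarial and multi-level verification (MLV) losses.
#
# The framework is a least-squares GAN. With Y a real reference ADC map and
# S = G(X) a synthesized map,
#   L_D     = E[(D(Y) - 1)^2] + E[(D(S))^2]
#   L_G^adv = E[(D(S) - 1)^2]
#   L_G^mlv = sum_{i in levels} theta_i * MSE(C_i(S), C_i(Y))
#   L_G     = L_G^adv + lambda1 * L_G^mlv
# where C_i are the feature maps of the frozen recognition model (level 0 is
# the raw image) and the theta_i are re-normalized once per epoch in
# proportion to the previous epoch's per-level losses, so the largest loss
# terms receive the largest weights. Expectations are means over all
# discriminator output scores of the batch.

#' Discriminator loss (least-squares GAN)
#'
#' @param d_real scores D(Y) on real references (any numeric array).
#' @param d_fake scores D(S) on synthesized images.
#' @return scalar loss `mean((d_real - 1)^2) + mean(d_fake^2)`.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  if (length(d_real) == 0L || length(d_fake) == 0L) stop("empty score batch")
  if (!all(is.finite(d_real)) || !all(is.finite(d_fake))) stop("non-finite scores")
  mean((d_real - 1)^2) + mean(d_fake^2)
}

#' Generator adversarial loss (least-squares GAN)
#'
#' @param d_fake scores D(S) on synthesized images.
#' @return scalar loss `mean((d_fake - 1)^2)`.
#' @export
generator_adv_loss <- function(d_fake) {
  if (length(d_fake) == 0L) stop("empty score batch")
  if (!all(is.finite(d_fake))) stop("non-finite scores")
  mean((d_fake - 1)^2)
}

#' Multi-level verification weights
#'
#' @param theta non-negative weights keyed by feature level; must sum to 1.
#' @param levels the feature levels the weights refer to.
#' @export
theta_weights <- function(theta = rep(1 / 4, 4), levels = c(0L, 1L, 3L, 5L)) {
  stopifnot(length(theta) == length(levels), all(theta >= 0))
  if (abs(sum(theta) - 1) > 1e-9) stop("theta must sum to 1")
  names(theta) <- as.character(levels)
  structure(theta, class = "theta_weights")
}

#' Extract multi-level features from the recognition model
#'
#' Level 0 is the raw image itself (identity feature); other levels are the
#' activations of the indexed conv units of the frozen classifier.
#'
#' @param model an `adcgan_recognizer`.
#' @param image a (H, W, 1, N) tensor (or matrix for a single slice).
#' @param keep keep forward caches (needed to backpropagate into the image).
#' @return list with `features` (named by level) and, if `keep`, the trunk
#'   forward record for backpropagation.
#' @export
extract_features <- function(model, image, keep = FALSE) {
  x <- as_tensor(image)
  levels <- model$spec$feature_levels
  conv_levels <- levels[levels > 0L]
  tr <- net_forward(model$trunk, x, keep = TRUE)
  feats <- list()
  for (lv in levels) {
    feats[[as.character(lv)]] <- if (lv == 0L) x else tr$outs[[model$taps[[as.character(lv)]]]]
  }
  if (!keep) tr <- NULL
  list(features = feats, trunk = tr)
}

#' Multi-level verification loss
#'
#' The per-level term is the squared L2 norm of the feature difference,
#' `||C_i(S) - C_i(Y)||^2_2`, averaged over the batch (`reduction = "sum"`,
#' the formula of the objective). `reduction = "mean"` instead averages over
#' all feature elements, which puts the levels on a common per-element scale
#' but — at the published loss weight — leaves the generator with almost no
#' reconstruction signal, so it is not used for training.
#'
#' @param features_s,features_y named lists of feature arrays (same levels and
#'   shapes), as returned by [extract_features()].
#' @param theta a [theta_weights()] vector over the same levels.
#' @param reduction per-level reduction over feature elements.
#' @return list with `loss` (weighted total) and `per_level` (unweighted
#'   per-level losses).
#' @export
mlv_loss <- function(features_s, features_y, theta,
                     reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  lev <- names(theta)
  if (!all(lev %in% names(features_s)) || !all(lev %in% names(features_y)))
    stop("feature levels do not match theta levels")
  per <- vapply(lev, function(l) {
    a <- features_s[[l]]; b <- features_y[[l]]
    if (!identical(dim(a), dim(b))) stop("feature shape mismatch at level ", l)
    nb <- if (length(dim(a)) == 4L) dim(a)[4] else 1L
    if (reduction == "sum") sum((a - b)^2) / nb else mean((a - b)^2)
  }, numeric(1))
  list(loss = sum(unclass(theta) * per), per_level = per)
}

#' Per-epoch update of the multi-level weights
#'
#' Weights are proportional to the previous epoch's per-level losses, so the
#' levels that are currently worst reconstructed are pushed hardest:
#' `theta_i = (L_i + eps) / sum_n (L_n + eps)`.
#'
#' @param prev_level_losses non-negative per-level losses of the previous epoch.
#' @param epsilon guard against an all-zero denominator.
#' @param levels feature levels the losses refer to.
#' @export
update_theta <- function(prev_level_losses, epsilon = 1e-8,
                         levels = c(0L, 1L, 3L, 5L)) {
  if (any(prev_level_losses < 0)) stop("negative per-level loss")
  w <- prev_level_losses + epsilon
  theta_weights(w / sum(w), levels = levels)
}

#' Total generator objective
#'
#' @param adv adversarial component.
#' @param mlv multi-level verification component.
#' @param config a [train_config()] supplying `lambda1`.
#' @export
generator_total_loss <- function(adv, mlv, config) {
  stopifnot(is.finite(adv), is.finite(mlv))
  adv + config$lambda1 * mlv
}
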