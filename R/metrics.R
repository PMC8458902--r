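# Full-reference image-quality metrics and the anatomical distortion measure.
#
# RMSE/PSNR are computed on [0, 1] normalized intensities. SSIM follows the
# original local-statistics formulation (11-tap Gaussian window, sigma 1.5,
# K1 = 0.01, K2 = 0.03, valid-window mean). FSIM combines phase-congruency
# similarity and gradient-magnitude similarity weighted by the maximum phase
# congruency; phase congruency uses a 4-scale x 4-orientation log-Gabor bank
# (minWavelength 6, mult 2, sigmaOnf 0.55) with k = 2 noise compensation, and
# gradients use the Scharr operator, on a joint [0, 255] rescale of the pair.

check_pair <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("image shape mismatch")
  list(a = a, b = b)
}

#' Root mean square error
#' @param a,b images of identical shape (normalized intensities).
#' @export
img_rmse <- function(a, b) {
  p <- check_pair(a, b)
  sqrt(mean((p$a - p$b)^2))
}

#' Peak signal-to-noise ratio (dB)
#'
#' Identical images yield `Inf` (to be excluded from aggregates with a count).
#'
#' @param a,b images of identical shape.
#' @param max_val peak intensity (1 for normalized images).
#' @export
img_psnr <- function(a, b, max_val = 1) {
  p <- check_pair(a, b)
  mse <- mean((p$a - p$b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

# Valid-window separable filter: returns K_r %*% x %*% t(K_c).
valid_filter_ops <- function(H, W, k) {
  n <- length(k)
  Kr <- matrix(0, H - n + 1L, H)
  for (i in seq_len(H - n + 1L)) Kr[i, i:(i + n - 1L)] <- k
  Kc <- matrix(0, W - n + 1L, W)
  for (i in seq_len(W - n + 1L)) Kc[i, i:(i + n - 1L)] <- k
  list(Kr = Kr, Kc = Kc)
}

#' Structural similarity index
#'
#' @param a,b images of identical shape on a `[0, max_val]` scale.
#' @param window Gaussian window size (odd).
#' @param sigma Gaussian window SD in pixels.
#' @param k1,k2 stabilization constants.
#' @param max_val dynamic range.
#' @return list with `mean` (the SSIM value) and `map` (valid-window map).
#' @export
img_ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                     max_val = 1) {
  p <- check_pair(a, b)
  if (window %% 2L == 0L) stop("window must be odd")
  if (any(dim(p$a) < window)) stop("image smaller than the SSIM window")
  g <- exp(-(seq_len(window) - (window + 1) / 2)^2 / (2 * sigma^2))
  g <- g / sum(g)
  ops <- valid_filter_ops(nrow(p$a), ncol(p$a), g)
  f <- function(x) ops$Kr %*% x %*% t(ops$Kc)
  c1 <- (k1 * max_val)^2; c2 <- (k2 * max_val)^2
  mu1 <- f(p$a); mu2 <- f(p$b)
  s11 <- f(p$a * p$a) - mu1^2
  s22 <- f(p$b * p$b) - mu2^2
  s12 <- f(p$a * p$b) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
         ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  list(mean = mean(map), map = map)
}

# ---- FSIM ----

# Phase congruency map (log-Gabor, Kovesi-style) for one image.
phase_congruency <- function(img, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                             k = 2, epsilon = 1e-4) {
  H <- nrow(img); W <- ncol(img)
  fx <- if (W %% 2L == 0L) (seq_len(W) - 1 - W / 2) / W else
    (seq_len(W) - 1 - (W - 1) / 2) / W
  fy <- if (H %% 2L == 0L) (seq_len(H) - 1 - H / 2) / H else
    (seq_len(H) - 1 - (H - 1) / 2) / H
  ishift <- function(v, n) { h <- ceiling(n / 2); c(v[(h + 1):n], v[1:h]) }
  fx <- ishift(fx, W); fy <- ishift(fy, H)
  X <- matrix(fx, H, W, byrow = TRUE)
  Y <- matrix(fy, H, W)
  radius <- sqrt(X^2 + Y^2); radius[1, 1] <- 1
  theta <- atan2(-Y, X)
  lowpass <- 1 / (1 + (radius / 0.45)^(2 * 15))

  log_gabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    f0 <- 1 / (min_wavelength * mult^(s - 1))
    lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2)) * lowpass
    lg[1, 1] <- 0
    log_gabor[[s]] <- lg
  }

  imfft <- fft(img)
  theta_sigma <- pi / norient / 1.2
  energy_all <- matrix(0, H, W)
  an_all <- matrix(0, H, W)

  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sin(theta) * cos(angl) - cos(theta) * sin(angl)
    dc <- cos(theta) * cos(angl) + sin(theta) * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    sumE <- sumO <- sumAn <- matrix(0, H, W)
    Es <- Os <- vector("list", nscale)
    tau <- 0
    for (s in seq_len(nscale)) {
      eo <- fft(imfft * (log_gabor[[s]] * spread), inverse = TRUE) / (H * W)
      e <- Re(eo); oimg <- Im(eo)
      an <- sqrt(e^2 + oimg^2)
      sumE <- sumE + e; sumO <- sumO + oimg; sumAn <- sumAn + an
      Es[[s]] <- e; Os[[s]] <- oimg
      if (s == 1L) tau <- median(an) / sqrt(log(4))
    }
    xenergy <- sqrt(sumE^2 + sumO^2) + epsilon
    meanE <- sumE / xenergy; meanO <- sumO / xenergy
    energy <- matrix(0, H, W)
    for (s in seq_len(nscale)) {
      energy <- energy + Es[[s]] * meanE + Os[[s]] * meanO -
        abs(Es[[s]] * meanO - Os[[s]] * meanE)
    }
    total_tau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    T <- (noise_mean + k * noise_sigma) / 1.7
    energy_all <- energy_all + pmax(energy - T, 0)
    an_all <- an_all + sumAn
  }
  energy_all / (an_all + epsilon)
}

# 3x3 convolution with replicated borders.
conv3 <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  pr <- function(i) pmin(pmax(i, 1), H)
  pc <- function(j) pmin(pmax(j, 1), W)
  out <- matrix(0, H, W)
  for (di in -1:1) for (dj in -1:1)
    out <- out + k[di + 2, dj + 2] * img[pr(seq_len(H) + di), pc(seq_len(W) + dj)]
  out
}

scharr_gradmag <- function(img) {
  kx <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3, 3, byrow = TRUE) / 16
  gx <- conv3(img, kx)
  gy <- conv3(img, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index
#'
#' Phase-congruency similarity times gradient-magnitude similarity, weighted
#' by the maximum phase congruency of the pair. Both images are jointly
#' rescaled to [0, 255]; a pair of flat images is defined as 1, a single flat
#' image against a structured one is an error.
#'
#' @param a,b images of identical shape (min dimension >= 32).
#' @param t1 phase-congruency stabilization constant.
#' @param t2 gradient stabilization constant (on the 0-255 scale).
#' @export
img_fsim <- function(a, b, t1 = 0.85, t2 = 160) {
  p <- check_pair(a, b)
  if (min(dim(p$a)) < 32L) stop("FSIM needs a minimum dimension of 32 pixels")
  flat_a <- sd(as.vector(p$a)) == 0
  flat_b <- sd(as.vector(p$b)) == 0
  if (flat_a && flat_b) return(1)
  if (flat_a || flat_b) stop("FSIM undefined when exactly one image is flat")
  rng <- range(c(p$a, p$b))
  g1 <- (p$a - rng[1]) / (rng[2] - rng[1]) * 255
  g2 <- (p$b - rng[1]) / (rng[2] - rng[1]) * 255
  f <- max(1L, round(min(dim(g1)) / 256))
  if (f > 1L) {
    g1 <- bilinear_resize(g1, dim(g1) %/% f)
    g2 <- bilinear_resize(g2, dim(g2) %/% f)
  }
  pc1 <- phase_congruency(g1)
  pc2 <- phase_congruency(g2)
  gm1 <- scharr_gradmag(g1)
  gm2 <- scharr_gradmag(g2)
  s_pc <- (2 * pc1 * pc2 + t1) / (pc1^2 + pc2^2 + t1)
  s_g <- (2 * gm1 * gm2 + t2) / (gm1^2 + gm2^2 + t2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

#' Prostate diameter distortion
#'
#' The anterior-posterior (AP) diameter is the row extent of the mask times
#' the row spacing; left-right (LR) analogous over columns. Returns absolute
#' differences versus the reference mask, plus the raw diameters.
#'
#' @param mask,ref_mask binary matrices (non-empty).
#' @param spacing mm per pixel (row, col).
#' @export
diameter_distortion <- function(mask, ref_mask, spacing = c(0.95, 0.95)) {
  if (!any(mask) || !any(ref_mask)) stop("empty mask")
  spacing <- rep(spacing, length.out = 2)
  diam <- function(m) {
    rr <- range(which(rowSums(m) > 0))
    cr <- range(which(colSums(m) > 0))
    c(ap = (rr[2] - rr[1] + 1) * spacing[1],
      lr = (cr[2] - cr[1] + 1) * spacing[2])
  }
  d <- diam(mask); dr <- diam(ref_mask)
  list(delta_ap = abs(d[["ap"]] - dr[["ap"]]),
       delta_lr = abs(d[["lr"]] - dr[["lr"]]),
       ap = d[["ap"]], lr = d[["lr"]],
       ap_ref = dr[["ap"]], lr_ref = dr[["lr"]])
}

#' Estimate a prostate mask from an ADC map
#'
#' Band-thresholds the map (prostate tissue ADC sits well above the near-zero
#' fitted values of the air background), applies a 3x3 majority filter twice
#' to remove isolated noise pixels, and keeps the connected component
#' containing (or nearest to) the grid center, where the gland sits.
#' Pre-smoothing is off by default: averaging the zero-clipped background
#' biases it upward into the tissue band.
#'
#' @param map an [adc_map()] or matrix in mm^2/s.
#' @param band (low, high) ADC band treated as prostate tissue.
#' @param smooth_sigma pre-smoothing in pixels.
#' @export
mask_from_adc <- function(map, band = c(0.4e-3, 1.95e-3), smooth_sigma = 0) {
  data <- if (inherits(map, "adc_map")) map$data else as.matrix(map)
  sm <- gauss_blur(data, smooth_sigma)
  m <- sm >= band[1] & sm <= band[2]
  ones <- matrix(1, 3, 3)
  for (i in 1:2) m <- conv3(m * 1, ones) >= 5
  if (!any(m)) return(m)
  ctr <- round(dim(m) / 2)
  if (!m[ctr[1], ctr[2]]) {
    pts <- which(m, arr.ind = TRUE)
    d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
    if (min(d2) > (min(dim(m)) / 4)^2) return(m & FALSE)
    ctr <- pts[which.min(d2), ]
  }
  flood_component(m, ctr)
}

# 4-connected component of `mask` containing `start` (row, col).
flood_component <- function(mask, start) {
  H <- nrow(mask); W <- ncol(mask)
  comp <- matrix(FALSE, H, W)
  stack <- integer(H * W)
  stack[1] <- (start[2] - 1L) * H + start[1]
  top <- 1L
  comp[stack[1]] <- TRUE
  while (top > 0L) {
    p <- stack[top]; top <- top - 1L
    r <- (p - 1L) %% H + 1L; c_ <- (p - 1L) %/% H + 1L
    for (q in c(if (r > 1L) p - 1L, if (r < H) p + 1L,
                if (c_ > 1L) p - H, if (c_ < W) p + H)) {
      if (mask[q] && !comp[q]) {
        comp[q] <- TRUE
        top <- top + 1L
        stack[top] <- q
      }
    }
  }
  comp
}
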