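# Deterministic preprocessing: resampling, intensity-based affine alignment,
# center cropping, rescaling to the unified training resolution, and intensity
# normalization. All interpolation is bilinear (nearest-neighbor for masks);
# no randomness anywhere in this module.

# Bilinear resize to an arbitrary shape with pixel-center alignment and
# clamped borders; constant images stay constant.
bilinear_resize <- function(img, out_shape, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  img <- as.matrix(img)
  H <- nrow(img); W <- ncol(img)
  Ho <- as.integer(round(out_shape[1])); Wo <- as.integer(round(out_shape[2]))
  stopifnot(Ho >= 1, Wo >= 1)
  if (Ho == H && Wo == W) return(img)
  rr <- (seq_len(Ho) - 0.5) * H / Ho + 0.5
  cc <- (seq_len(Wo) - 0.5) * W / Wo + 0.5
  rr <- pmin(pmax(rr, 1), H); cc <- pmin(pmax(cc, 1), W)
  if (interp == "nearest")
    return(img[round(rr), round(cc), drop = FALSE])
  r0 <- floor(rr); r1 <- pmin(r0 + 1, H); fr <- rr - r0
  c0 <- floor(cc); c1 <- pmin(c0 + 1, W); fc <- cc - c0
  a <- img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
       img[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
       img[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
       img[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}

#' Resample an image grid to a new voxel spacing
#'
#' The output matrix size is `round(n_in * spacing_in / spacing_out)` per axis;
#' interpolation is bilinear (`nearest` for masks).
#'
#' @param img image matrix.
#' @param spacing_in,spacing_out mm per pixel (row, col); scalars are recycled.
#' @param interp interpolation scheme.
#' @export
resample_image <- function(img, spacing_in, spacing_out,
                           interp = c("linear", "nearest")) {
  if (any(spacing_in <= 0) || any(spacing_out <= 0)) stop("non-positive spacing")
  spacing_in <- rep(spacing_in, length.out = 2)
  spacing_out <- rep(spacing_out, length.out = 2)
  if (isTRUE(all.equal(spacing_in, spacing_out))) return(as.matrix(img))
  out_shape <- round(dim(as.matrix(img)) * spacing_in / spacing_out)
  bilinear_resize(img, out_shape, interp = match.arg(interp))
}

#' Symmetric center crop
#'
#' Odd remainders give the extra removed pixel to the leading side.
#'
#' @param img image matrix.
#' @param crop_shape target (rows, cols), each no larger than the image.
#' @export
center_crop <- function(img, crop_shape) {
  img <- as.matrix(img)
  d <- dim(img)
  if (any(crop_shape > d)) stop("crop larger than image")
  start <- ceiling((d - crop_shape) / 2) + 1
  img[start[1]:(start[1] + crop_shape[1] - 1),
      start[2]:(start[2] + crop_shape[2] - 1), drop = FALSE]
}

#' Rescale to the unified training resolution
#'
#' @param img image matrix.
#' @param target output (rows, cols); default 224 x 224.
#' @param interp interpolation scheme.
#' @export
rescale_to_unified <- function(img, target = c(224L, 224L),
                               interp = c("linear", "nearest")) {
  bilinear_resize(img, target, interp = match.arg(interp))
}

#' Normalize intensities to [0, 1]
#'
#' `minmax` maps min to 0 and max to 1; `percentile` clips at the 1st/99th
#' percentiles first (robust to isolated hot pixels). A constant image maps to
#' all zeros.
#'
#' @param img image matrix.
#' @param mode normalization mode.
#' @param probs clip percentiles for `percentile` mode.
#' @export
normalize_intensity <- function(img, mode = c("minmax", "percentile"),
                                probs = c(0.01, 0.99)) {
  mode <- match.arg(mode)
  img <- as.matrix(img)
  if (!all(is.finite(img))) stop("non-finite intensities")
  if (mode == "percentile") {
    q <- quantile(img, probs, names = FALSE, type = 7)
    img <- pmin(pmax(img, q[1]), q[2])
  }
  rng <- range(img)
  if (rng[1] == rng[2]) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Affine parameters
#'
#' @param translation (row, col) in pixels.
#' @param scale (row, col) multiplicative scale (> 0).
#' @param rotation degrees, |rotation| <= 45.
#' @export
affine_params <- function(translation = c(0, 0), scale = c(1, 1), rotation = 0) {
  stopifnot(all(scale > 0), abs(rotation) <= 45)
  structure(list(translation = translation, scale = rep(scale, length.out = 2),
                 rotation = rotation), class = "affine_params")
}

# Sample `moving` under the affine model: the warped image approximates the
# fixed frame via warped(p) = moving(c + R(-rot) ((p - c) / scale) - t).
apply_affine <- function(moving, params, center = (dim(as.matrix(moving)) + 1) / 2) {
  img <- as.matrix(moving)
  H <- nrow(img); W <- ncol(img)
  th <- -params$rotation * pi / 180
  pr <- matrix(seq_len(H), H, W) - center[1]
  pc <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  qr <- pr / params$scale[1]; qc <- pc / params$scale[2]
  sr <- cos(th) * qr - sin(th) * qc + center[1] - params$translation[1]
  sc <- sin(th) * qr + cos(th) * qc + center[2] - params$translation[2]
  sr <- pmin(pmax(sr, 1), H); sc <- pmin(pmax(sc, 1), W)
  r0 <- floor(sr); r1 <- pmin(r0 + 1, H); fr <- sr - r0
  c0 <- floor(sc); c1 <- pmin(c0 + 1, W); fc <- sc - c0
  idx <- function(r, c) matrix(img[cbind(as.vector(r), as.vector(c))], H, W)
  idx(r0, c0) * (1 - fr) * (1 - fc) + idx(r1, c0) * fr * (1 - fc) +
    idx(r0, c1) * (1 - fr) * fc + idx(r1, c1) * fr * fc
}

ncc <- function(a, b) {
  va <- as.vector(a); vb <- as.vector(b)
  if (sd(vb) == 0) stop("flat fixed image: correlation undefined")
  if (sd(va) == 0) return(-1)
  cor(va, vb)
}

#' Intensity-based affine alignment
#'
#' Maximizes normalized cross-correlation between the warped moving image and
#' the fixed image by a coarse grid search over translation and per-axis scale
#' (optionally rotation), followed by deterministic coordinate-descent
#' refinement with shrinking steps.
#'
#' @param moving,fixed image matrices of identical shape and spacing.
#' @param max_translation_px search half-range for translation.
#' @param scale_range (low, high) search interval for each scale factor.
#' @param max_rotation_deg half-range for rotation; 0 disables the rotation
#'   search.
#' @return list with `params` ([affine_params()]), `warped`, and `ncc`.
#' @export
align_affine <- function(moving, fixed, max_translation_px = 6,
                         scale_range = c(0.9, 1.1), max_rotation_deg = 0) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(identical(dim(moving), dim(fixed)))
  if (sd(as.vector(fixed)) == 0) stop("flat fixed image: correlation undefined")

  score <- function(t1, t2, s1, s2, rot) {
    ncc(apply_affine(moving, affine_params(c(t1, t2), c(s1, s2), rot)), fixed)
  }
  # stage 1: integer translation grid at identity scale
  tgrid <- seq(-max_translation_px, max_translation_px, by = 1)
  best <- c(t1 = 0, t2 = 0, s1 = 1, s2 = 1, rot = 0)
  best_v <- -Inf
  for (t1 in tgrid) for (t2 in tgrid) {
    v <- score(t1, t2, 1, 1, 0)
    if (v > best_v) { best_v <- v; best[c("t1", "t2")] <- c(t1, t2) }
  }
  # stage 2: per-axis scale grids at the best translation
  sgrid <- seq(scale_range[1], scale_range[2], by = 0.02)
  for (s1 in sgrid) {
    v <- score(best["t1"], best["t2"], s1, best["s2"], best["rot"])
    if (v > best_v) { best_v <- v; best["s1"] <- s1 }
  }
  for (s2 in sgrid) {
    v <- score(best["t1"], best["t2"], best["s1"], s2, best["rot"])
    if (v > best_v) { best_v <- v; best["s2"] <- s2 }
  }
  if (max_rotation_deg > 0) {
    for (rot in seq(-max_rotation_deg, max_rotation_deg, by = 1)) {
      v <- score(best["t1"], best["t2"], best["s1"], best["s2"], rot)
      if (v > best_v) { best_v <- v; best["rot"] <- rot }
    }
  }
  # stage 3: coordinate descent with shrinking steps
  steps <- list(t = c(0.5, 0.25, 0.125), s = c(0.01, 0.005, 0.0025),
                r = c(0.5, 0.25, 0.125))
  for (lev in 1:3) {
    for (rep in 1:3) {
      improved <- FALSE
      for (par in c("t1", "t2", "s1", "s2", if (max_rotation_deg > 0) "rot")) {
        st <- switch(substr(par, 1, 1), t = steps$t[lev], s = steps$s[lev],
                     r = steps$r[lev])
        for (dir in c(-1, 1)) {
          cand <- best
          cand[par] <- cand[par] + dir * st
          if (cand["s1"] <= 0 || cand["s2"] <= 0) next
          v <- score(cand["t1"], cand["t2"], cand["s1"], cand["s2"], cand["rot"])
          if (v > best_v + 1e-12) { best_v <- v; best <- cand; improved <- TRUE }
        }
      }
      if (!improved) break
    }
  }
  params <- affine_params(c(best[["t1"]], best[["t2"]]),
                          c(best[["s1"]], best[["s2"]]), best[["rot"]])
  list(params = params, warped = apply_affine(moving, params), ncc = best_v)
}
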