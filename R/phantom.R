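# Zonal prostate phantom simulator.
#
# Anatomy is a nested-ellipse model on a 2-D axial grid: a prostate ellipse
# containing an anterior transitional-zone (TZ) ellipse and a peripheral-zone
# (PZ) rim, an optional lesion disc in the posterior gland, and a
# negligible-signal (air-like) background so the gland boundary is
# recoverable from any of the fitted/synthesized ADC maps. Tissue ADC levels follow the
# published prostate literature: PZ 1.43, TZ 1.20, benign lesion 0.98,
# malignant lesion 0.61 (x 10^-3 mm^2/s). Per case the tissue ADC is drawn
# once from Normal(mean, SD), held constant within the tissue, and modulated
# by a small smooth texture field. DWI signal follows mono-exponential decay
# S(b) = S0 exp(-b * ADC) with Rician magnitude noise.
#
# The degraded ("full-FOV") arm emulates echo-planar phase-encode distortion:
# a smooth random displacement field applied along the row (anterior-
# posterior) axis only, Gaussian blur, a downsample/upsample resolution loss,
# and higher noise.

MM2_PER_CM2 <- 100

#' Phantom specification
#'
#' @param grid_shape integer (rows, cols) of the axial slice.
#' @param voxel_spacing mm per pixel (row, col).
#' @param zone_adc_means,zone_adc_sds named ADC means/SDs in mm^2/s for
#'   `pz`, `tz`, `benign`, `malignant`.
#' @param lesion_present,lesion_class,lesion_radius_mm lesion disc settings.
#' @param s0_level baseline signal at b = 0 (arbitrary units).
#' @param noise_sigma_clean,noise_sigma_degraded Rician noise SD as a fraction
#'   of `s0_level` for the clean (zoomed-FOV-like) and degraded arms.
#' @param max_displacement_px peak of the row-direction displacement field.
#' @param blur_sigma_px Gaussian blur applied to the degraded arm.
#' @param downsample_factor resolution loss of the degraded arm (>= 1).
#' @param b_values diffusion weightings in s/mm^2.
#' @param texture_amp relative amplitude of the smooth ADC texture field.
#' @param s0_texture_amp relative amplitude of the smooth S0 texture field.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L),
                         voxel_spacing = c(0.95, 0.95),
                         zone_adc_means = c(pz = 1.43e-3, tz = 1.20e-3,
                                            benign = 0.98e-3, malignant = 0.61e-3),
                         zone_adc_sds = c(pz = 0.17e-3, tz = 0.16e-3,
                                          benign = 0.18e-3, malignant = 0.11e-3),
                         lesion_present = TRUE,
                         lesion_class = c("malignant", "benign"),
                         lesion_radius_mm = 6.5,
                         s0_level = 1000,
                         noise_sigma_clean = 0.02,
                         noise_sigma_degraded = 0.03,
                         max_displacement_px = 4,
                         blur_sigma_px = 1.2,
                         downsample_factor = 2,
                         b_values = c(50, 1000, 1500),
                         texture_amp = 0.05,
                         s0_texture_amp = 0.10) {
  lesion_class <- match.arg(lesion_class)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 16L),
            all(voxel_spacing > 0),
            all(zone_adc_means > 0), all(zone_adc_means < 4e-3),
            all(zone_adc_sds >= 0),
            lesion_radius_mm > 0, s0_level > 0,
            noise_sigma_clean >= 0, noise_sigma_degraded >= 0,
            max_displacement_px >= 0, blur_sigma_px >= 0,
            downsample_factor >= 1,
            all(b_values >= 0), !is.unsorted(b_values, strictly = TRUE))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = voxel_spacing,
                 zone_adc_means = zone_adc_means, zone_adc_sds = zone_adc_sds,
                 lesion_present = isTRUE(lesion_present),
                 lesion_class = lesion_class,
                 lesion_radius_mm = lesion_radius_mm,
                 s0_level = s0_level,
                 noise_sigma_clean = noise_sigma_clean,
                 noise_sigma_degraded = noise_sigma_degraded,
                 max_displacement_px = max_displacement_px,
                 blur_sigma_px = blur_sigma_px,
                 downsample_factor = downsample_factor,
                 b_values = b_values,
                 texture_amp = texture_amp,
                 s0_texture_amp = s0_texture_amp),
            class = "phantom_spec")
}

#' Multi-b-value DWI container
#'
#' @param data array indexed (b-index, row, col), non-negative magnitudes.
#' @param b_values strictly increasing b-values, one per leading index.
#' @param voxel_spacing mm per pixel (row, col).
#' @export
dwi_volume <- function(data, b_values, voxel_spacing) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(b_values),
            all(data >= 0), !is.unsorted(b_values, strictly = TRUE),
            all(b_values >= 0))
  structure(list(data = data, b_values = b_values,
                 voxel_spacing = voxel_spacing),
            class = "dwi_volume")
}

# ---- geometry helpers ----

ellipse_mask <- function(shape, center, radii) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / radii[1])^2 + ((c_ - center[2]) / radii[2])^2 <= 1
}

disc_mask <- function(shape, center, radius_px) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c_ - center[2])^2 <= radius_px^2
}

# Separable Gaussian blur with replicated borders; sigma in pixels.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, rad), seq_len(n), rep(n, rad))
  x <- img[pad_idx(nrow(img)), , drop = FALSE]
  x <- apply(x, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
  x <- x[(rad + 1):(rad + nrow(img)), , drop = FALSE]
  x <- x[, pad_idx(ncol(img)), drop = FALSE]
  x <- t(apply(x, 1, function(row) as.numeric(stats::filter(row, k, sides = 2))))
  x[, (rad + 1):(rad + ncol(img)), drop = FALSE]
}

# Smooth seeded random field, blurred white noise rescaled to peak `peak`.
smooth_field <- function(shape, peak, smooth_sigma, seed) {
  if (peak == 0) return(matrix(0, shape[1], shape[2]))
  f <- with_seed(seed, matrix(rnorm(prod(shape)), shape[1], shape[2]))
  f <- gauss_blur(f, smooth_sigma)
  f * (peak / max(abs(f)))
}

# Shift image content along the row axis by a per-pixel displacement field
# (linear interpolation, clamped borders). Used for phase-encode distortion.
warp_rows <- function(img, disp, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  r <- matrix(seq_len(H), H, W) + disp
  r <- pmin(pmax(r, 1), H)
  cidx <- rep(seq_len(W), each = H)
  if (interp == "nearest") {
    return(matrix(img[cbind(as.vector(round(r)), cidx)], H, W))
  }
  r0 <- floor(r); r1 <- pmin(r0 + 1, H); fr <- r - r0
  v0 <- img[cbind(as.vector(r0), cidx)]
  v1 <- img[cbind(as.vector(r1), cidx)]
  matrix(v0 * (1 - as.vector(fr)) + v1 * as.vector(fr), H, W)
}

# ---- operations ----

#' Simulate a multi-b-value DWI acquisition
#'
#' Mono-exponential decay `S(b) = S0 * exp(-b * ADC)` with Rician magnitude
#' noise: each voxel becomes `sqrt((S + n1)^2 + n2^2)` with
#' `n1, n2 ~ Normal(0, (noise_sigma * s0_level)^2)`.
#'
#' @param adc ADC grid in mm^2/s (matrix or [adc_map()]).
#' @param s0 signal-at-b0 grid, same shape.
#' @param b_values b-values in s/mm^2.
#' @param noise_sigma noise SD as a fraction of `s0_level`.
#' @param seed integer seed.
#' @param s0_level reference signal level for the noise scale.
#' @param voxel_spacing mm per pixel.
#' @return a [dwi_volume()].
#' @export
simulate_dwi <- function(adc, s0, b_values, noise_sigma = 0, seed = 1L,
                         s0_level = max(s0), voxel_spacing = c(0.95, 0.95)) {
  if (inherits(adc, "adc_map")) { voxel_spacing <- adc$voxel_spacing; adc <- adc$data }
  if (any(b_values < 0)) stop("negative b-value")
  stopifnot(all(adc >= 0), all(s0 >= 0), noise_sigma >= 0,
            identical(dim(adc), dim(s0)))
  H <- nrow(adc); W <- ncol(adc); B <- length(b_values)
  data <- array(0, dim = c(B, H, W))
  for (i in seq_len(B)) data[i, , ] <- s0 * exp(-b_values[i] * adc)
  if (noise_sigma > 0) {
    sig <- noise_sigma * s0_level
    noise <- with_seed(seed, list(n1 = rnorm(B * H * W, sd = sig),
                                  n2 = rnorm(B * H * W, sd = sig)))
    data <- array(sqrt((as.vector(data) + noise$n1)^2 + noise$n2^2),
                  dim = c(B, H, W))
  }
  dwi_volume(data, b_values, voxel_spacing)
}

#' Degrade a clean DWI volume into a full-FOV-like acquisition
#'
#' Applies, in order: a smooth random displacement field along the row
#' (anterior-posterior) axis whose peak magnitude equals
#' `spec$max_displacement_px`; Gaussian blur of `spec$blur_sigma_px`;
#' a downsample/upsample resolution loss of `spec$downsample_factor`; and
#' Rician noise at `spec$noise_sigma_degraded`. With all four set to zero /
#' one the output is bit-identical to the input. The displacement field is
#' attached as field `displacement` so masks can be transported consistently.
#'
#' @param dwi a [dwi_volume()].
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @export
degrade_to_ffov <- function(dwi, spec, seed = 1L) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(spec, "phantom_spec"))
  seeds <- child_seeds(seed, 2)
  B <- dim(dwi$data)[1]; H <- dim(dwi$data)[2]; W <- dim(dwi$data)[3]
  disp <- smooth_field(c(H, W), spec$max_displacement_px, smooth_sigma = 8, seeds[1])
  data <- dwi$data
  for (i in seq_len(B)) {
    sl <- data[i, , ]
    if (spec$max_displacement_px > 0) sl <- warp_rows(sl, disp)
    if (spec$blur_sigma_px > 0) sl <- gauss_blur(sl, spec$blur_sigma_px)
    if (spec$downsample_factor > 1) {
      lo <- bilinear_resize(sl, round(c(H, W) / spec$downsample_factor))
      sl <- bilinear_resize(lo, c(H, W))
    }
    data[i, , ] <- pmax(sl, 0)
  }
  if (spec$noise_sigma_degraded > 0) {
    sig <- spec$noise_sigma_degraded * spec$s0_level
    noise <- with_seed(seeds[2], list(n1 = rnorm(length(data), sd = sig),
                                      n2 = rnorm(length(data), sd = sig)))
    data <- array(sqrt((as.vector(data) + noise$n1)^2 + noise$n2^2), dim = dim(data))
  }
  out <- dwi_volume(data, dwi$b_values, dwi$voxel_spacing)
  out$displacement <- disp
  out
}

#' Generate one paired phantom case
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; identical (spec, seed) gives a bit-identical case.
#' @return a `phantom_case`: ground-truth ADC, tissue masks, clean and
#'   degraded DWI arms, warped masks for the degraded arm, and the label.
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  seeds <- child_seeds(seed, 6)
  shape <- spec$grid_shape
  sp <- spec$voxel_spacing
  center <- (shape + 1) / 2

  # anatomy (pixel radii derived from mm so geometry is spacing-invariant)
  pro_r <- c(15, 19) / sp        # prostate AP/LR half-diameters in px
  if (any(pro_r >= shape / 2 - 1.5)) stop("grid too small for the prostate ellipse")
  prostate <- ellipse_mask(shape, center, pro_r)
  tz <- ellipse_mask(shape, center - c(0.22 * pro_r[1], 0), 0.55 * pro_r)
  tz <- tz & prostate
  pz <- prostate & !tz

  lesion <- matrix(FALSE, shape[1], shape[2])
  label <- "none"
  if (spec$lesion_present) {
    label <- spec$lesion_class
    r_px <- spec$lesion_radius_mm / mean(sp)
    off <- with_seed(seeds[1], runif(1, -0.2, 0.2)) * pro_r[2]
    lcen <- c(center[1] + 0.40 * pro_r[1], center[2] + off)
    lesion <- disc_mask(shape, lcen, r_px)
    if (any(lesion & !prostate))
      stop("geometry error: lesion of radius ", spec$lesion_radius_mm,
           " mm does not fit inside the prostate ellipse")
    pz <- pz & !lesion   # zone masks exclude the lesion
    tz <- tz & !lesion
  }

  # per-case tissue ADC draws (held constant within tissue)
  draws <- with_seed(seeds[2], {
    v <- rnorm(length(spec$zone_adc_means), spec$zone_adc_means, spec$zone_adc_sds)
    names(v) <- names(spec$zone_adc_means)
    pmin(pmax(v, 0.05e-3), 3.95e-3)
  })

  adc <- matrix(1e-4, shape[1], shape[2])  # air: near-zero diffusivity
  adc[pz] <- draws[["pz"]]
  adc[tz] <- draws[["tz"]]
  if (any(lesion)) adc[lesion] <- draws[[label]]
  tex <- smooth_field(shape, spec$texture_amp, smooth_sigma = 3, seeds[3])
  adc[prostate] <- pmin(pmax((adc * (1 + tex))[prostate], 0.05e-3), 3.95e-3)

  s0 <- matrix(0.02, shape[1], shape[2])   # air: negligible signal
  s0[prostate] <- 1.0
  s0 <- s0 * spec$s0_level
  s0tex <- smooth_field(shape, spec$s0_texture_amp, smooth_sigma = 4, seeds[4])
  s0 <- s0 * (1 + s0tex)

  true_adc <- adc_map(adc, voxel_spacing = sp, provenance = "ground_truth")
  clean <- simulate_dwi(adc, s0, spec$b_values, spec$noise_sigma_clean,
                        seed = seeds[5], s0_level = spec$s0_level,
                        voxel_spacing = sp)
  noisefree <- simulate_dwi(adc, s0, spec$b_values, 0,
                            s0_level = spec$s0_level, voxel_spacing = sp)
  degraded <- degrade_to_ffov(noisefree, spec, seed = seeds[6])

  warp_mask <- function(m) {
    if (is.null(degraded$displacement) || spec$max_displacement_px == 0) return(m)
    warp_rows(m * 1, degraded$displacement, interp = "nearest") > 0.5
  }
  masks <- list(prostate = prostate, pz = pz, tz = tz, lesion = lesion,
                background = !prostate)
  masks_degraded <- list(prostate = warp_mask(prostate), lesion = warp_mask(lesion))

  structure(list(true_adc = true_adc, masks = masks,
                 masks_degraded = masks_degraded,
                 clean_dwi = clean, degraded_dwi = degraded,
                 s0 = s0, label = label, seed = as.integer(seed), spec = spec),
            class = "phantom_case")
}

#' Generate a labelled phantom cohort
#'
#' @param n_benign,n_malignant,n_volunteer exact case counts per label
#'   (volunteers carry no lesion).
#' @param spec a [phantom_spec()]; the lesion class is overridden per case.
#' @param seed integer seed.
#' @export
make_cohort <- function(n_benign, n_malignant, n_volunteer = 0L,
                        spec = phantom_spec(), seed = 1L) {
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant),
              rep("none", n_volunteer))
  seeds <- child_seeds(seed, max(1L, length(labels)))
  lapply(seq_along(labels), function(i) {
    sp <- spec
    if (labels[i] == "none") sp$lesion_present <- FALSE
    else sp$lesion_class <- labels[i]
    make_phantom(sp, seed = seeds[i])
  })
}

# ---- simulated reader ROIs ----

#' Circular reader ROI
#'
#' @param center (row, col) in pixels.
#' @param radius_px radius in pixels.
#' @param spacing mm per pixel.
#' @param reader_id,repetition identifiers of the simulated measurement.
#' @export
reader_roi <- function(center, radius_px, spacing, reader_id = 1L,
                       repetition = 1L) {
  area_cm2 <- pi * (radius_px * mean(spacing))^2 / MM2_PER_CM2
  structure(list(center = center, radius_px = radius_px, area_cm2 = area_cm2,
                 reader_id = as.integer(reader_id),
                 repetition = as.integer(repetition)),
            class = "reader_roi")
}

# Distance (in px) from each TRUE pixel to the nearest FALSE pixel boundary.
mask_interior_depth <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  if (!any(mask)) return(out)
  comp <- which(!mask | row(mask) %in% c(1, H) | col(mask) %in% c(1, W), arr.ind = TRUE)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(comp) == 0L) { out[mask] <- Inf; return(out) }
  for (i in seq_len(nrow(pts))) {
    d2 <- (comp[, 1] - pts[i, 1])^2 + (comp[, 2] - pts[i, 2])^2
    out[pts[i, 1], pts[i, 2]] <- sqrt(min(d2))
  }
  out
}

#' Place a simulated reader ROI inside a mask
#'
#' The ROI is centered at the mask centroid plus a seeded jitter; if a circle
#' of the minimum requested area does not fit there (inside the mask eroded by
#' one pixel), the deepest interior point is used instead. The radius targets
#' the midpoint of `area_bounds_cm2` and shrinks, if necessary, down to the
#' lower bound.
#'
#' @param mask binary matrix (the tissue to measure).
#' @param spacing mm per pixel.
#' @param area_bounds_cm2 (low, high) admissible ROI area.
#' @param jitter_px uniform placement jitter in pixels.
#' @param reader_id,repetition identifiers.
#' @param seed integer seed (jitter differs across readers/repetitions through
#'   the seed).
#' @export
simulate_reader_rois <- function(mask, spacing, area_bounds_cm2 = c(0.5, 0.8),
                                 jitter_px = 1, reader_id = 1L,
                                 repetition = 1L, seed = 1L) {
  if (!any(mask)) stop("empty mask")
  stopifnot(all(area_bounds_cm2 > 0), area_bounds_cm2[1] <= area_bounds_cm2[2])
  sp <- mean(spacing)
  r_min <- sqrt(area_bounds_cm2[1] * MM2_PER_CM2 / pi) / sp
  r_tgt <- sqrt(mean(area_bounds_cm2) * MM2_PER_CM2 / pi) / sp

  depth <- mask_interior_depth(mask)
  jit <- with_seed(seed, runif(2, -jitter_px, jitter_px))
  pts <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(pts)
  cand <- centroid + jit
  ci <- round(cand)
  feas_at <- function(p) {
    p <- pmin(pmax(p, 1), dim(mask))
    if (!mask[p[1], p[2]]) return(0)
    depth[p[1], p[2]] - 1  # erode by one pixel
  }
  max_r <- feas_at(ci)
  if (max_r < r_min) {
    best <- pts[which.max(depth[pts]), ]
    cand <- best + jit * 0.5
    ci <- pmin(pmax(round(cand), 1), dim(mask))
    max_r <- feas_at(ci)
  }
  if (max_r < r_min) {
    have <- pi * (max(max_r, 0) * sp)^2 / MM2_PER_CM2
    stop(sprintf(paste0("mask too small for the minimum ROI area: supports ",
                        "%.3f cm^2, minimum requested is %.3f cm^2"),
                 have, area_bounds_cm2[1]))
  }
  reader_roi(center = as.numeric(cand), radius_px = min(r_tgt, max_r),
             spacing = spacing, reader_id = reader_id, repetition = repetition)
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case: %dx%d px, label = %s, seed = %d\n",
              x$spec$grid_shape[1], x$spec$grid_shape[2], x$label, x$seed))
  invisible(x)
}
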