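# Mono-exponential ADC fitting and ROI summaries.
#
# ADC maps are reconstructed from multi-b-value DWI by ordinary least squares
# of log-signal against b: ln S(b) = ln S0 - b * ADC, the standard scanner
# reconstruction. Signals are floored before the log to avoid -Inf in
# background air, and the fitted map is clipped to a physiological prostate
# range (default 0 to 4e-3 mm^2/s).

#' ADC map container
#'
#' @param data per-voxel ADC grid in mm^2/s.
#' @param voxel_spacing mm per pixel (row, col).
#' @param provenance one of `fitted`, `synthesized`, `ground_truth`.
#' @param clip_range (low, high) admissible ADC in mm^2/s.
#' @export
adc_map <- function(data, voxel_spacing = c(0.95, 0.95),
                    provenance = c("fitted", "synthesized", "ground_truth"),
                    clip_range = c(0, 4e-3)) {
  provenance <- match.arg(provenance)
  data <- as.matrix(data)
  stopifnot(clip_range[1] < clip_range[2])
  if (any(data < clip_range[1] - 1e-15) || any(data > clip_range[2] + 1e-15))
    stop("ADC data outside clip_range")
  structure(list(data = data, voxel_spacing = voxel_spacing,
                 provenance = provenance, clip_range = clip_range),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("adc_map (%s): %dx%d px, median %.3f x10^-3 mm^2/s\n",
              x$provenance, nrow(x$data), ncol(x$data),
              1e3 * median(x$data)))
  invisible(x)
}

#' Fit an ADC map from multi-b-value DWI
#'
#' Per-voxel ordinary least squares of `ln S(b)` on `b`; the negated slope is
#' the ADC. Signals below `floor` (default `1e-6 * max(signal)`) are floored
#' before the log; the result is clipped to `clip_range`. The number of
#' floored samples is attached as attribute `n_floored`.
#'
#' @param dwi a [dwi_volume()] with at least two b-values.
#' @param clip_range (low, high) admissible ADC in mm^2/s.
#' @param floor signal floor; `NULL` for the default.
#' @return an [adc_map()] with provenance `fitted`.
#' @export
fit_adc <- function(dwi, clip_range = c(0, 4e-3), floor = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  b <- dwi$b_values
  if (length(b) < 2L) stop("ADC fitting needs at least 2 b-values")
  if (is.null(floor)) floor <- 1e-6 * max(dwi$data)
  if (floor <= 0) floor <- .Machine$double.xmin
  d <- dim(dwi$data)
  s <- matrix(dwi$data, nrow = length(b))   # b x voxels
  n_floored <- sum(s < floor)
  s[s < floor] <- floor
  ls <- log(s)
  bc <- b - mean(b)
  slope <- as.vector(crossprod(bc, ls)) / sum(bc^2)
  adc <- pmin(pmax(-slope, clip_range[1]), clip_range[2])
  out <- adc_map(matrix(adc, d[2], d[3]), voxel_spacing = dwi$voxel_spacing,
                 provenance = "fitted", clip_range = clip_range)
  attr(out, "n_floored") <- n_floored
  out
}

#' Mean ADC within a circular reader ROI
#'
#' Arithmetic mean over pixels whose centers lie within the circle.
#'
#' @param map an [adc_map()] (or plain matrix).
#' @param roi a [reader_roi()].
#' @export
roi_mean <- function(map, roi) {
  data <- if (inherits(map, "adc_map")) map$data else as.matrix(map)
  H <- nrow(data); W <- ncol(data)
  if (roi$center[1] < 1 || roi$center[1] > H || roi$center[2] < 1 ||
      roi$center[2] > W)
    stop("ROI center outside the grid")
  r <- matrix(seq_len(H), H, W)
  c_ <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- (r - roi$center[1])^2 + (c_ - roi$center[2])^2 <= roi$radius_px^2
  if (!any(inside)) stop("empty ROI: no pixel center falls inside the circle")
  mean(data[inside])
}
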