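# NIfTI + JSON-sidecar I/O for DWI volumes, ADC maps, and phantom cases.
# Images are stored as .nii.gz with spacing in the header; acquisition
# metadata (b-values, provenance, labels) lives in a JSON sidecar next to
# each image, and masks are stored as a single integer label volume.

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

# plain numeric array, stripped of RNifti header attributes
nifti_array <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  array(as.numeric(a), dim = dim(a))
}

#' Write / read a DWI volume as NIfTI (+ JSON sidecar with b-values)
#' @param dwi a [dwi_volume()].
#' @param path output `.nii.gz` path.
#' @export
write_dwi <- function(dwi, path) {
  stopifnot(inherits(dwi, "dwi_volume"))
  d <- dim(dwi$data)
  arr <- aperm(dwi$data, c(2, 3, 1))  # store as (row, col, b)
  img <- RNifti::asNifti(arr, pixdim = c(dwi$voxel_spacing, 1))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(b_values = dwi$b_values,
                            voxel_spacing = dwi$voxel_spacing),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(path) {
  arr <- nifti_array(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  dwi_volume(aperm(arr, c(3, 1, 2)), b_values = as.numeric(meta$b_values),
             voxel_spacing = as.numeric(meta$voxel_spacing))
}

#' Write / read an ADC map as NIfTI (+ JSON sidecar with provenance)
#'
#' Values are stored in mm^2/s (display convention x 10^-3 recorded in the
#' sidecar).
#'
#' @param map an [adc_map()].
#' @param path output `.nii.gz` path.
#' @export
write_adc <- function(map, path) {
  stopifnot(inherits(map, "adc_map"))
  img <- RNifti::asNifti(map$data, pixdim = map$voxel_spacing)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(provenance = map$provenance,
                            clip_range = map$clip_range,
                            voxel_spacing = map$voxel_spacing,
                            units = "mm^2/s",
                            display_convention = "x 10^-3 mm^2/s"),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_adc
#' @export
read_adc <- function(path) {
  arr <- nifti_array(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  adc_map(arr, voxel_spacing = as.numeric(meta$voxel_spacing),
          provenance = meta$provenance,
          clip_range = as.numeric(meta$clip_range))
}

#' Write / read a phantom case directory
#'
#' Writes both DWI arms, the ground-truth ADC, a mask label volume
#' (1 = PZ, 2 = TZ, 3 = lesion, 0 = background), and a JSON metadata file
#' (label, seed, spec).
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created).
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dwi(case$clean_dwi, file.path(dir, "clean_dwi.nii.gz"))
  deg <- case$degraded_dwi; deg$displacement <- NULL
  write_dwi(deg, file.path(dir, "degraded_dwi.nii.gz"))
  write_adc(case$true_adc, file.path(dir, "true_adc.nii.gz"))
  lab <- matrix(0L, nrow(case$true_adc$data), ncol(case$true_adc$data))
  lab[case$masks$pz] <- 1L
  lab[case$masks$tz] <- 2L
  lab[case$masks$lesion] <- 3L
  RNifti::writeNifti(RNifti::asNifti(lab, pixdim = case$spec$voxel_spacing),
                     file.path(dir, "masks.nii.gz"))
  spec <- case$spec; class(spec) <- NULL
  jsonlite::write_json(list(label = case$label, seed = case$seed, spec = spec),
                       file.path(dir, "case.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"), simplifyVector = TRUE)
  lab <- nifti_array(file.path(dir, "masks.nii.gz"))
  masks <- list(pz = lab == 1L, tz = lab == 2L, lesion = lab == 3L)
  masks$prostate <- masks$pz | masks$tz | masks$lesion
  masks$background <- !masks$prostate
  structure(list(true_adc = read_adc(file.path(dir, "true_adc.nii.gz")),
                 masks = masks,
                 clean_dwi = read_dwi(file.path(dir, "clean_dwi.nii.gz")),
                 degraded_dwi = read_dwi(file.path(dir, "degraded_dwi.nii.gz")),
                 label = meta$label, seed = meta$seed),
            class = "phantom_case")
}
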