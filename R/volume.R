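#' 3D volume carrier for ADC maps and binary lesion masks
#'
#' An `adc_volume` wraps a 3D array together with its voxel spacing and
#' (optionally) the NIfTI affine. ADC values are carried throughout the package
#' in units of 1e-6 mm^2/s, i.e. the number 555 rather than 5.55e-4 — the scale
#' on which clinical thresholds are quoted.
#'
#' @param data numeric 3D array. For `kind = "mask"` values must be in {0, 1};
#'   anything non-zero is coerced to 1 with a warning. For `kind = "adc"` all
#'   finite values must be >= 0.
#' @param spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm;
#'   strictly positive.
#' @param kind `"adc"` or `"mask"`.
#' @param affine optional 4x4 voxel-to-world matrix kept for provenance and
#'   grid comparison; the package never resamples or reorients.
#' @return an object of class `adc_volume`.
#' @examples
#' m <- adc_volume(array(0L, c(4, 4, 2)), spacing = c(0.6, 0.6, 6.5), kind = "mask")
#' dim(m$data)
#' @export
adc_volume <- function(data, spacing, kind = c("adc", "mask"), affine = NULL) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive mm values", call. = FALSE)
  if (kind == "mask") {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1))) {
      warning("mask contains values outside {0, 1}; binarising with (value > 0)",
              call. = FALSE)
      data <- array(as.numeric(data > 0), dim(data))
    }
    storage.mode(data) <- "integer"
  } else {
    fin <- data[is.finite(data)]
    if (any(fin < 0))
      stop("ADC volume contains negative values", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, kind = kind, affine = affine),
            class = "adc_volume")
}

#' @export
print.adc_volume <- function(x, ...) {
  cat(sprintf("<adc_volume> kind=%s  dim=%s  spacing=%s mm\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Read a NIfTI-1 volume as an ADC map or binary mask
#'
#' Spacing is taken from the NIfTI header (`pixdim`), the affine is kept for
#' grid comparison. Mask files holding values outside {0, 1} are binarised by
#' `value > 0` with a warning. Only 3D volumes are accepted: co-registration is
#' assumed done upstream and 4D inputs are an error, not something to squeeze.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind `"adc"` or `"mask"`.
#' @return an [adc_volume].
#' @seealso [write_volume()], [assert_same_grid()]
#' @export
read_volume <- function(path, kind = c("adc", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- tryCatch(structure(RNifti::xform(img), class = NULL),
                     error = function(e) NULL)
  adc_volume(array(as.numeric(img), d), spacing = spacing, kind = kind,
             affine = affine)
}

#' Write a volume to NIfTI-1
#'
#' Masks are stored as unsigned 8-bit integers, ADC maps as 32-bit float, so
#' that write/read round trips are bit-exact for masks and exact to float32
#' precision for ADC.
#'
#' @param vol an [adc_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "adc_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  datatype <- if (vol$kind == "mask") "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Check that two volumes live on the same voxel grid
#'
#' The package never resamples: pre/post masks and the ADC map must already be
#' co-registered onto one grid, and any mismatch is an error rather than a
#' repair. Shapes must be identical; spacing components must agree within a
#' relative tolerance.
#'
#' @param a,b [adc_volume] objects.
#' @param tolerance relative spacing tolerance (default `1e-3`).
#' @return `TRUE` invisibly if compatible, otherwise an error of class
#'   `adcrev_grid_error` naming both grids.
#' @export
assert_same_grid <- function(a, b, tolerance = 1e-3) {
  stopifnot(inherits(a, "adc_volume"), inherits(b, "adc_volume"))
  da <- dim(a$data); db <- dim(b$data)
  fmt <- function(d, s) sprintf("[%s] @ (%s) mm", paste(d, collapse = ","),
                                paste(format(s), collapse = ","))
  if (!identical(da, db))
    stop(errorCondition(
      sprintf("grid shape mismatch: %s vs %s", fmt(da, a$spacing), fmt(db, b$spacing)),
      class = c("adcrev_grid_error", "error")))
  rel <- abs(a$spacing - b$spacing) / pmax(a$spacing, b$spacing)
  if (any(rel > tolerance))
    stop(errorCondition(
      sprintf("voxel spacing mismatch: %s vs %s", fmt(da, a$spacing), fmt(db, b$spacing)),
      class = c("adcrev_grid_error", "error")))
  invisible(TRUE)
}

#' Convert a voxel count to millilitres
#'
#' @param count non-negative voxel count.
#' @param spacing mm triple (dx, dy, dz).
#' @return volume in mL: `count * dx * dy * dz / 1000`.
#' @examples
#' voxels_to_ml(428, c(0.6, 0.6, 6.5)) # 1.00152
#' @export
voxels_to_ml <- function(count, spacing) {
  if (any(count < 0)) stop("voxel count must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  count * prod(spacing) / 1000
}
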