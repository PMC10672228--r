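#' Volumetric image container
#'
#' A minimal voxel-grid container used throughout the pipeline: a 3D array of
#' intensities (rows x columns x slices) with physical in-plane/slice spacing
#' in millimetres, an origin, and a modality label (`"ct"`, `"kv_cbct"`,
#' `"mv_cbct"`, `"mask"`, ...). 2D input is promoted to a single-slice volume.
#'
#' @param data numeric matrix or 3D array of voxel values (HU for images,
#'   0/1 for masks).
#' @param spacing numeric length-3: in-plane row/column spacing and slice
#'   thickness, mm. A single value is recycled in-plane with the same slice
#'   thickness.
#' @param origin numeric length-3 physical coordinate of the first voxel, mm.
#' @param modality character label.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = "unknown") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop_synthmv("image data must be 2D or 3D")
  if (length(spacing) == 1L) spacing <- c(spacing, spacing, spacing)
  if (length(spacing) == 2L) spacing <- c(spacing[1], spacing[1], spacing[2])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_synthmv("spacing must be strictly positive")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), modality = as.character(modality)),
    class = "image_volume"
  )
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
as.array.image_volume <- function(x, ...) x$data

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s  %d x %d x %d  spacing %.3g/%.3g/%.3g mm  [%.4g, %.4g]\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

check_congruent <- function(a, b, what = "images") {
  if (!identical(dim(a$data), dim(b$data)))
    stop_synthmv("%s have different grid shapes", what)
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop_synthmv("%s have different voxel spacing", what)
  invisible(TRUE)
}

# carry an optional validity mask (non-fill region) through operations
volume_validity <- function(v) {
  attr(v, "validity") %||% array(TRUE, dim = dim(v$data))
}

set_volume_validity <- function(v, valid) {
  attr(v, "validity") <- valid
  v
}

#' Read a volume from a NIfTI file
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality modality label to attach.
#' @return An [image_volume()].
#' @export
load_volume <- function(path, modality = "unknown") {
  if (!file.exists(path)) stop_synthmv("no such file: %s", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop_synthmv("malformed NIfTI file %s: %s", path, conditionMessage(e)))
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))   # strip NIfTI header attributes
  if (length(dim(dat)) == 2L) dat <- array(dat, dim = c(dim(dat), 1L))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L) pd <- c(pd, rep(1, 3 - length(pd)))
  orig <- attr(img, "origin") %||% c(0, 0, 0)
  image_volume(dat, spacing = pd[1:3], origin = as.numeric(orig)[1:3],
               modality = modality)
}

#' Write a volume to a NIfTI file
#'
#' Spacing and origin are preserved; integer-valued masks survive a round
#' trip voxel-identically.
#'
#' @param v an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  stopifnot(is_image_volume(v))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
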