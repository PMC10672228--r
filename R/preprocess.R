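#' Clip volume intensities to a HU window
#'
#' kV CT/CBCT images use [-1000, 2000] HU; MV CBCT uses [-1000, 400] HU.
#'
#' @param image an [image_volume()].
#' @param lo,hi window bounds, HU (`lo < hi`).
#' @return The clipped [image_volume()], metadata preserved.
#' @export
clip_intensities <- function(image, lo = -1000, hi = 2000) {
  stopifnot(is_image_volume(image))
  if (lo >= hi) stop_synthmv("clip window requires lo < hi (got %g, %g)", lo, hi)
  out <- image
  out$data <- pmin(pmax(image$data, lo), hi)
  attr(out, "validity") <- attr(image, "validity")
  out
}

#' Kilovoltage and megavoltage clip windows
#' @return named numeric length-2 vector.
#' @export
kv_clip_range <- function() c(lo = -1000, hi = 2000)

#' @rdname kv_clip_range
#' @export
mv_clip_range <- function() c(lo = -1000, hi = 400)

#' Body mask from an MV image by thresholding
#'
#' Voxels above `threshold` (default -400 HU), then per-slice largest
#' connected component and hole filling. The mask restricts training patch
#' centres to the body.
#'
#' @param mv_image an [image_volume()] in HU.
#' @param threshold HU.
#' @return Object of class `body_mask`: `mask` (binary array),
#'   `threshold_used`, `component_policy`.
#' @export
compute_body_mask <- function(mv_image, threshold = -400) {
  stopifnot(is_image_volume(mv_image))
  raw <- mv_image$data > threshold
  if (!any(raw))
    stop_synthmv("empty body mask at threshold %g HU; consider lowering the threshold", threshold)
  d <- dim(raw)
  mask <- array(FALSE, dim = d)
  for (s in seq_len(d[3]))
    mask[, , s] <- largest_component_fill(raw[, , s])
  structure(list(mask = mask, threshold_used = threshold,
                 component_policy = "per-slice largest component + hole fill"),
            class = "body_mask")
}

# largest 4-connected component of a binary slice, holes filled
largest_component_fill <- function(bw) {
  if (!any(bw)) return(bw)
  lab <- EBImage::bwlabel(matrix(as.numeric(bw), nrow(bw), ncol(bw)))
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  comp <- lab == keep
  filled <- EBImage::fillHull(matrix(as.numeric(comp), nrow(bw), ncol(bw)))
  filled > 0.5
}

#' Crop aligned volumes to their common field of view
#'
#' Each volume carries a validity mask (the non-fill region left by
#' [resample()]; all-true for native volumes). All volumes are cropped to
#' the tight bounding box of the intersection of validity masks, giving
#' identical output shapes.
#'
#' @param images list of congruent [image_volume()] objects.
#' @return list of cropped [image_volume()] objects.
#' @export
crop_to_overlap <- function(images) {
  stopifnot(length(images) >= 1)
  for (im in images) check_congruent(images[[1]], im)
  inter <- Reduce(`&`, lapply(images, volume_validity))
  if (!any(inter)) stop_synthmv("validity masks have empty intersection")
  idx <- which(inter, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2]); ss <- range(idx[, 3])
  lapply(images, function(im) {
    out <- image_volume(im$data[rr[1]:rr[2], cc[1]:cc[2], ss[1]:ss[2], drop = FALSE],
                        spacing = im$spacing, origin = im$origin,
                        modality = im$modality)
    set_volume_validity(out, inter[rr[1]:rr[2], cc[1]:cc[2], ss[1]:ss[2], drop = FALSE])
  })
}

#' Normalize a clipped volume into [-1, 1] for the networks
#'
#' Affine map of `[lo, hi]` onto `[-1, 1]`; [denormalize_from_network()]
#' inverts it exactly up to float rounding.
#'
#' @param image [image_volume()] already clipped to `[lo, hi]`.
#' @param lo,hi the clip window, HU.
#' @return [image_volume()] with values in [-1, 1] and the window stored in
#'   the `norm_range` attribute.
#' @export
normalize_for_network <- function(image, lo = -1000, hi = 2000) {
  stopifnot(is_image_volume(image))
  out <- image
  out$data <- 2 * (image$data - lo) / (hi - lo) - 1
  attr(out, "norm_range") <- c(lo = lo, hi = hi)
  attr(out, "validity") <- attr(image, "validity")
  out
}

#' @rdname normalize_for_network
#' @param x normalized values in [-1, 1] (array or volume).
#' @export
denormalize_from_network <- function(x, lo = -1000, hi = 2000) {
  v <- if (is_image_volume(x)) x$data else x
  out <- (v + 1) / 2 * (hi - lo) + lo
  if (is_image_volume(x)) { x$data <- out; x } else out
}

#' Extract paired 2D training patches at body-restricted centres
#'
#' Samples `n_patches` centres uniformly from body-mask voxels (seeded);
#' patches whose footprint would exceed the grid are shifted minimally to
#' fit, preserving the centre-in-body guarantee. Input and target patches
#' are cut at identical coordinates.
#'
#' @param input_vol,target_vol congruent normalized [image_volume()]s
#'   (kV-domain input, MV-domain target).
#' @param body a [compute_body_mask()] result (computed on the MV image).
#' @param patch_size square patch side, pixels.
#' @param n_patches number of patches to draw.
#' @param seed integer.
#' @param case_id label carried into the output.
#' @return tibble with columns `case_id`, `slice`, `center_i`, `center_j`,
#'   `row0`, `col0`, `input` and `target` (list columns of matrices).
#' @export
extract_patches <- function(input_vol, target_vol, body, patch_size = 256L,
                            n_patches = 32L, seed = 1L, case_id = "case") {
  check_congruent(input_vol, target_vol, "input/target volumes")
  d <- dim(input_vol$data)
  if (patch_size > d[1] || patch_size > d[2])
    stop_synthmv("patch_size %d exceeds grid extent %d x %d", patch_size, d[1], d[2])
  if (!identical(dim(body$mask), d))
    stop_synthmv("body mask is not congruent with the volumes")
  centers <- which(body$mask, arr.ind = TRUE)
  if (nrow(centers) == 0) stop_synthmv("body mask is empty")
  pick <- with_seed(seed, centers[sample.int(nrow(centers), n_patches,
                                             replace = TRUE), , drop = FALSE])
  half <- patch_size %/% 2
  rows <- purrr::map(seq_len(n_patches), function(k) {
    ci <- pick[k, 1]; cj <- pick[k, 2]; s <- pick[k, 3]
    r0 <- min(max(ci - half, 1L), d[1] - patch_size + 1L)
    c0 <- min(max(cj - half, 1L), d[2] - patch_size + 1L)
    tibble::tibble(
      case_id = case_id, slice = s, center_i = ci, center_j = cj,
      row0 = r0, col0 = c0,
      input = list(input_vol$data[r0:(r0 + patch_size - 1L),
                                  c0:(c0 + patch_size - 1L), s]),
      target = list(target_vol$data[r0:(r0 + patch_size - 1L),
                                    c0:(c0 + patch_size - 1L), s]))
  })
  dplyr::bind_rows(rows)
}
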