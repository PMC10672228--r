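#' Rigid in-plane transform
#'
#' The pipeline is 2D-slice based: volumes are thin extruded stacks, so a
#' rigid transform is one in-plane rotation plus a 2-vector translation about
#' a physical rotation centre. A transform maps fixed-frame physical
#' coordinates `p` to moving-frame coordinates `R (p - c) + c + t`.
#'
#' @param angle_deg rotation, degrees (counter-clockwise in row/column space).
#' @param translation numeric length-2, mm.
#' @param center numeric length-2 rotation centre, mm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(angle_deg = 0, translation = c(0, 0),
                            center = c(0, 0)) {
  stopifnot(length(translation) == 2L, length(center) == 2L)
  structure(list(angle_deg = as.numeric(angle_deg),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotmat2 <- function(angle_deg) {
  th <- angle_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a rigid transform to physical points
#' @param transform a [rigid_transform()].
#' @param pts n x 2 matrix of physical coordinates, mm.
#' @return n x 2 matrix of mapped coordinates.
#' @export
transform_points <- function(transform, pts) {
  pts <- rbind(pts)
  R <- rotmat2(transform$angle_deg)
  sweep(t(R %*% t(sweep(pts, 2, transform$center))), 2,
        -(transform$center + transform$translation))
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b [rigid_transform()] objects sharing a rotation centre.
#' @return The composed [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  if (max(abs(a$center - b$center)) > 1e-9)
    stop_synthmv("transforms must share a rotation centre to compose")
  Ra <- rotmat2(a$angle_deg)
  rigid_transform(a$angle_deg + b$angle_deg,
                  as.numeric(Ra %*% b$translation) + a$translation,
                  a$center)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rinv <- rotmat2(-transform$angle_deg)
  rigid_transform(-transform$angle_deg,
                  -as.numeric(Rinv %*% transform$translation),
                  transform$center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle %.4g deg, t = (%.4g, %.4g) mm, centre (%.4g, %.4g) mm\n",
              x$angle_deg, x$translation[1], x$translation[2],
              x$center[1], x$center[2]))
  invisible(x)
}

#' Resample a volume under a rigid transform onto a reference grid
#'
#' Linear interpolation for intensities; voxels whose sampling point falls
#' outside the moving image are set to `fill_value` (air by default) and
#' excluded from the volume's validity mask, which downstream cropping uses.
#'
#' @param moving [image_volume()] to resample.
#' @param transform [rigid_transform()] mapping reference coordinates into
#'   `moving` coordinates.
#' @param reference [image_volume()] defining the output grid (defaults to
#'   the moving image's own grid).
#' @param fill_value intensity for out-of-field voxels (default -1000 HU).
#' @param nearest use nearest-neighbour interpolation (for masks).
#' @return [image_volume()] on the reference grid.
#' @export
resample <- function(moving, transform, reference = moving,
                     fill_value = -1000, nearest = FALSE) {
  stopifnot(is_image_volume(moving), inherits(transform, "rigid_transform"))
  sp <- reference$spacing[1]
  if (abs(reference$spacing[2] - sp) > 1e-9)
    stop_synthmv("in-plane spacing must be isotropic")
  d <- dim(reference$data)
  th <- transform$angle_deg * pi / 180
  # pixel-unit parameters for the C++ kernel (0-based pixel centres)
  cxy <- transform$center / sp
  txy <- transform$translation / sp
  out <- array(fill_value, dim = d)
  valid <- array(FALSE, dim = d)
  nslice <- min(d[3], dim(moving$data)[3])
  ca <- cos(th); sa <- sin(th)
  if (nearest) {
    # nearest-neighbour sampling, vectorized in R (used for masks)
    X <- matrix(seq_len(d[1]) - 1, d[1], d[2])
    Y <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
    xs <- round(cxy[1] + ca * (X - cxy[1]) - sa * (Y - cxy[2]) + txy[1])
    ys <- round(cxy[2] + sa * (X - cxy[1]) + ca * (Y - cxy[2]) + txy[2])
    md <- dim(moving$data)
    ok <- xs >= 0 & xs <= md[1] - 1 & ys >= 0 & ys <= md[2] - 1
    idx <- cbind(xs[ok] + 1, ys[ok] + 1)
    for (s in seq_len(nslice)) {
      sl <- moving$data[, , s]
      o <- matrix(fill_value, d[1], d[2])
      o[ok] <- sl[idx]
      out[, , s] <- o
      valid[, , s] <- ok
    }
  } else {
    for (s in seq_len(nslice)) {
      r <- cpp_resample_rigid2d(moving$data[, , s], ca, sa, txy[1], txy[2],
                                cxy[1], cxy[2], fill_value)
      out[, , s] <- r$img
      valid[, , s] <- r$valid > 0.5
    }
  }
  res <- image_volume(out, spacing = reference$spacing,
                      origin = reference$origin, modality = moving$modality)
  set_volume_validity(res, valid)
}

#' Physical centre of an image grid
#' @param v an [image_volume()].
#' @return length-2 in-plane physical centre, mm.
#' @export
volume_center <- function(v) {
  d <- dim(v$data)
  (c(d[1], d[2]) - 1) / 2 * v$spacing[1:2]
}

#' Serialize / deserialize a rigid transform as JSON
#'
#' The file records the convention: the transform maps fixed-image physical
#' coordinates (mm) to moving-image coordinates via `R (p - c) + c + t`,
#' angle in degrees.
#' @param transform a [rigid_transform()].
#' @param path output path.
#' @return `path` (write) or a [rigid_transform()] (read).
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(
    convention = "p_moving = R(angle_deg) %*% (p_fixed - center) + center + translation; mm, degrees",
    angle_deg = transform$angle_deg,
    translation_mm = transform$translation,
    center_mm = transform$center
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$angle_deg, x$translation_mm, x$center_mm)
}
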