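#' Implanted-device description
#'
#' A pacemaker-like device is modelled as a simple (non-self-intersecting)
#' closed polygon of high attenuation, optionally with a thin lead polyline.
#' Coordinates are in device-local millimetres; placement into a phantom is
#' done by [phantom_spec()].
#'
#' @param outline n x 2 matrix of polygon vertices, mm (closed implicitly).
#' @param density_hu device attenuation; must exceed bone (default 3000 HU,
#'   a plausible pre-clip value for a titanium-canned generator).
#' @param lead_curve optional n x 2 polyline, mm.
#' @param device_id label.
#' @return Object of class `device_spec`.
#' @export
device_spec <- function(outline, density_hu = 3000, lead_curve = NULL,
                        device_id = "device") {
  outline <- rbind(outline)
  if (nrow(outline) < 3L) stop_synthmv("device outline needs >= 3 vertices")
  if (density_hu < 2000) stop_synthmv("device density must be >= 2000 HU")
  if (!polygon_is_simple(outline))
    stop_synthmv("device outline is self-intersecting")
  structure(list(outline = outline, density_hu = density_hu,
                 lead_curve = lead_curve, device_id = device_id),
            class = "device_spec")
}

# segment-intersection scan; adjacent edges share endpoints and are skipped
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Parametric thorax-phantom specification
#'
#' Describes one phantom/device combination: a body ellipse containing two
#' lung ellipses and a spine ellipse, a tissue-equivalent bolus sheet of
#' stated thickness over the anterior surface, and a device polygon placed
#' flat on the anterior chest under the bolus. Attenuations are piecewise
#' constant per tissue class and must be ordered air < lung < soft < bone <
#' device.
#'
#' @param body_axes length-2 semi-axes of the body ellipse, mm.
#' @param lung_regions list of `list(center =, axes =)` ellipses, mm.
#' @param spine_region `list(center =, axes =)`, mm.
#' @param base_intensities named HU values for `air`, `lung`, `soft`, `bone`,
#'   `bolus`.
#' @param bolus_thickness bolus sheet thickness, mm (default 5).
#' @param device a [device_spec()] or `NULL`.
#' @param device_center in-image centre for the device polygon, mm; default
#'   places it on the anterior chest surface under the bolus.
#' @param pixel_spacing isotropic in-plane spacing, mm per pixel.
#' @param slice_thickness mm.
#' @param grid_shape pixels per in-plane axis (square grid).
#' @param n_slices number of (extruded) slices.
#' @param phantom_id label.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_axes = c(95, 120),
                         lung_regions = list(
                           list(center = c(10, -52), axes = c(52, 38)),
                           list(center = c(10, 52), axes = c(52, 38))),
                         spine_region = list(center = c(62, 0), axes = c(16, 16)),
                         base_intensities = c(air = -1000, lung = -700,
                                              soft = 40, bone = 700, bolus = 10),
                         bolus_thickness = 5,
                         device = NULL,
                         device_center = NULL,
                         pixel_spacing = 4,
                         slice_thickness = 4,
                         grid_shape = 64L,
                         n_slices = 4L,
                         phantom_id = "phantom") {
  if (any(body_axes <= 0)) stop_synthmv("body semi-axes must be positive")
  for (lg in lung_regions) if (any(lg$axes <= 0))
    stop_synthmv("lung semi-axes must be positive")
  if (any(spine_region$axes <= 0)) stop_synthmv("spine semi-axes must be positive")
  req <- c("air", "lung", "soft", "bone")
  if (!all(req %in% names(base_intensities)))
    stop_synthmv("base_intensities must name air, lung, soft, bone")
  bi <- base_intensities
  if (!(bi["air"] < bi["lung"] && bi["lung"] < bi["soft"] && bi["soft"] < bi["bone"]))
    stop_synthmv("intensities must be ordered air < lung < soft < bone")
  if (!is.null(device) && device$density_hu <= bi["bone"])
    stop_synthmv("device density must exceed bone intensity")
  structure(list(body_axes = body_axes, lung_regions = lung_regions,
                 spine_region = spine_region, base_intensities = bi,
                 bolus_thickness = bolus_thickness, device = device,
                 device_center = device_center,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 grid_shape = as.integer(grid_shape),
                 n_slices = as.integer(n_slices),
                 phantom_id = phantom_id),
            class = "phantom_spec")
}

# physical (mm) coordinates of pixel centres; grid centre at FOV centre
grid_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

in_ellipse <- function(X, Y, center, axes) {
  ((X - center[1]) / axes[1])^2 + ((Y - center[2]) / axes[2])^2 <= 1
}

# even-odd rule point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2])) / 2
}

# Default anterior placement: device centred left-right at the given lateral
# offset, its top edge one bolus-thickness under the anterior body surface.
place_device <- function(spec) {
  dv <- spec$device
  if (is.null(dv)) return(NULL)
  ctr <- spec$device_center
  if (is.null(ctr)) {
    fov <- (spec$grid_shape - 1) * spec$pixel_spacing / 2
    out <- dv$outline
    h <- max(out[, 1]) - min(out[, 1])
    # anterior surface of the body ellipse at the lateral midline (row axis
    # points posterior); sit the device just under bolus + a small margin
    x_surface <- fov - spec$body_axes[1]
    ctr <- c(x_surface + spec$bolus_thickness + h / 2 + 2, fov)
  }
  out <- sweep(dv$outline, 2, -(ctr - colMeans(dv$outline)))
  out
}

#' Render the piecewise-constant attenuation map of a phantom
#'
#' Rasterizes the nested ellipses (body, lungs, spine), the anterior bolus
#' layer, and the device polygon at its stated attenuation, on the
#' specification's grid. The exact device raster is returned alongside the
#' image, as is the analytic body+bolus raster (used by body-mask tests).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` ([image_volume()]), `device_mask`,
#'   `body_mask` (binary arrays congruent with the image).
#' @export
render_attenuation_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape
  sp <- spec$pixel_spacing
  g <- grid_coords(n, sp)
  X <- matrix(g, n, n)
  Y <- matrix(g, n, n, byrow = TRUE)
  fov_c <- (n - 1) * sp / 2
  bi <- spec$base_intensities
  img <- matrix(bi[["air"]], n, n)

  body <- in_ellipse(X, Y, c(fov_c, fov_c), spec$body_axes)
  # bolus: expanded ellipse shell, anterior (low row coordinate) half only
  shell <- in_ellipse(X, Y, c(fov_c, fov_c),
                      spec$body_axes + spec$bolus_thickness) & !body
  bolus <- shell & (X < fov_c)
  img[body] <- bi[["soft"]]
  img[bolus] <- bi[["bolus"]] %||% bi[["soft"]]
  for (lg in spec$lung_regions)
    img[in_ellipse(X, Y, c(fov_c, fov_c) + lg$center, lg$axes)] <- bi[["lung"]]
  img[in_ellipse(X, Y, c(fov_c, fov_c) + spec$spine_region$center,
                 spec$spine_region$axes)] <- bi[["bone"]]

  dev_mask <- matrix(FALSE, n, n)
  if (!is.null(spec$device)) {
    poly <- place_device(spec)
    if (min(poly) < min(g) || max(poly[, 1]) > max(g) || max(poly[, 2]) > max(g))
      stop_synthmv("device polygon extends outside the image grid (rows %.1f..%.1f, cols %.1f..%.1f mm)",
                   min(poly[, 1]), max(poly[, 1]), min(poly[, 2]), max(poly[, 2]))
    inside_body <- points_in_polygon(poly[, 1], poly[, 2],
                                     ellipse_polygon(c(fov_c, fov_c),
                                                     spec$body_axes + spec$bolus_thickness))
    if (!all(inside_body))
      stop_synthmv("device polygon of '%s' lies outside the body+bolus surface",
                   spec$device$device_id)
    dev_mask <- matrix(points_in_polygon(as.vector(X), as.vector(Y), poly), n, n)
    if (!is.null(spec$device$lead_curve)) {
      lc <- sweep(spec$device$lead_curve, 2,
                  -(colMeans(poly) - colMeans(spec$device$outline)))
      lead <- draw_polyline(matrix(FALSE, n, n), lc, g, TRUE)
      dev_mask <- dev_mask | lead
    }
    img[dev_mask] <- spec$device$density_hu
  }

  vol <- array(rep(img, spec$n_slices), dim = c(n, n, spec$n_slices))
  dev3 <- array(rep(dev_mask, spec$n_slices), dim = c(n, n, spec$n_slices))
  body3 <- array(rep(body | bolus, spec$n_slices), dim = c(n, n, spec$n_slices))
  list(image = image_volume(vol, spacing = c(sp, sp, spec$slice_thickness),
                            modality = "mu_map"),
       device_mask = dev3, body_mask = body3)
}

ellipse_polygon <- function(center, axes, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + axes[1] * cos(th), center[2] + axes[2] * sin(th))
}

# burn a thin polyline into the raster at the given value; diagonal steps
# are bridged so the rasterized chain stays 4-connected
draw_polyline <- function(img, pts, g, value) {
  sp <- g[2] - g[1]
  for (k in seq_len(nrow(pts) - 1)) {
    a <- pts[k, ]; b <- pts[k + 1, ]
    L <- max(2, ceiling(sqrt(sum((b - a)^2)) / (sp / 4)))
    t <- seq(0, 1, length.out = L)
    xi <- round((a[1] + t * (b[1] - a[1])) / sp) + 1
    yi <- round((a[2] + t * (b[2] - a[2])) / sp) + 1
    keep <- c(TRUE, diff(xi) != 0 | diff(yi) != 0)
    xi <- xi[keep]; yi <- yi[keep]
    if (length(xi) > 1) {
      diag_step <- which(abs(diff(xi)) == 1 & abs(diff(yi)) == 1)
      if (length(diag_step)) {
        xi <- c(xi, xi[diag_step + 1])
        yi <- c(yi, yi[diag_step])
      }
    }
    ok <- xi >= 1 & xi <= nrow(img) & yi >= 1 & yi <= ncol(img)
    img[cbind(xi[ok], yi[ok])] <- value
  }
  img
}

#' Built-in device library
#'
#' Ten synthetic pacemaker outlines of varying size and shape (rounded can
#' shapes approximated by polygons), each with a short lead stub. Purely
#' parametric stand-ins for the study's ten physical devices.
#'
#' @param density_hu device attenuation, HU.
#' @return named list of [device_spec()] objects.
#' @export
default_device_library <- function(density_hu = 3000) {
  shapes <- list(
    d01 = c(22, 30), d02 = c(20, 34), d03 = c(24, 26), d04 = c(18, 30),
    d05 = c(22, 36), d06 = c(26, 30), d07 = c(20, 26), d08 = c(24, 34),
    d09 = c(18, 26), d10 = c(26, 36)
  )
  out <- list()
  for (id in names(shapes)) {
    hw <- shapes[[id]] / 2
    k <- match(id, names(shapes))
    # octagonal can with a corner chamfer that varies by device
    ch <- 0.25 + 0.05 * (k %% 4)
    h <- hw[1]; w <- hw[2]
    poly <- rbind(
      c(-h, -w * (1 - ch)), c(-h * (1 - ch), -w), c(h * (1 - ch), -w),
      c(h, -w * (1 - ch)), c(h, w * (1 - ch)), c(h * (1 - ch), w),
      c(-h * (1 - ch), w), c(-h, w * (1 - ch))
    )
    lead <- rbind(c(h * 0.6, w), c(h * 0.9, w + 6 + k))
    out[[id]] <- device_spec(poly, density_hu = density_hu,
                             lead_curve = lead, device_id = id)
  }
  out
}

#' Built-in phantom library
#'
#' Four thorax-phantom geometries (differing body and lung dimensions),
#' parametric stand-ins for the study's anthropomorphic and 3D-printed
#' phantoms.
#'
#' @param grid_shape,pixel_spacing,slice_thickness,n_slices grid settings
#'   forwarded to [phantom_spec()].
#' @return named list of [phantom_spec()] objects (device slot empty).
#' @export
default_phantom_library <- function(grid_shape = 64L, pixel_spacing = 4,
                                    slice_thickness = 4, n_slices = 4L) {
  fov <- (grid_shape - 1) * pixel_spacing
  # scale geometry to the field of view so one library serves both profiles
  s <- fov / 252
  mk <- function(id, body, lungdx, lungax, spine_r) {
    phantom_spec(
      body_axes = body * s,
      lung_regions = list(
        list(center = c(10, -lungdx) * s, axes = lungax * s),
        list(center = c(10, lungdx) * s, axes = lungax * s)),
      spine_region = list(center = c(body[1] - 33, 0) * s,
                          axes = c(spine_r, spine_r) * s),
      pixel_spacing = pixel_spacing, slice_thickness = slice_thickness,
      grid_shape = grid_shape, n_slices = n_slices, phantom_id = id)
  }
  list(
    p1 = mk("p1", c(95, 120), 52, c(52, 38), 15),
    p2 = mk("p2", c(88, 112), 48, c(48, 35), 14),
    p3 = mk("p3", c(100, 116), 50, c(55, 36), 16),
    p4 = mk("p4", c(92, 104), 45, c(50, 33), 15)
  )
}
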