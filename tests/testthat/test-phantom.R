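test_that("attenuation map without a device contains nothing above bone", {
  lib <- default_phantom_library()
  r <- render_attenuation_map(lib$p2)
  expect_lte(max(r$image$data), lib$p2$base_intensities[["bone"]])
  expect_false(any(r$device_mask))
})

test_that("device raster agrees with an independent convex-polygon scan", {
  # device outlines are convex octagons: a point is inside iff it lies on
  # one side of every edge -- an algorithm independent of the even-odd
  # rasterizer used by the renderer
  fx <- fixture_render()
  spec <- fx$spec
  spec$device$lead_curve <- NULL        # the lead is rasterized separately
  # off-lattice placement so no pixel centre sits exactly on a polygon edge
  # (where inside/outside conventions legitimately differ)
  spec$device_center <- c(49.37, 126.43)
  r <- render_attenuation_map(spec)
  poly <- synthmv:::place_device(spec)
  n <- spec$grid_shape; sp <- spec$pixel_spacing
  g <- (seq_len(n) - 1) * sp
  inside_convex <- function(px, py) {
    nv <- nrow(poly)
    sgn <- 0
    for (e in seq_len(nv)) {
      a <- poly[e, ]; b <- poly[e %% nv + 1, ]
      cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
      if (abs(cr) < 1e-12) next
      if (sgn == 0) sgn <- sign(cr)
      else if (sign(cr) != sgn) return(FALSE)
    }
    TRUE
  }
  count <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (inside_convex(g[i], g[j])) count <- count + 1L
  expect_equal(sum(r$device_mask[, , 1]), count)
})

test_that("device mask physical area tracks the analytic polygon area across resolutions", {
  lib4 <- default_phantom_library(grid_shape = 64L, pixel_spacing = 4)
  lib2 <- default_phantom_library(grid_shape = 128L, pixel_spacing = 2)
  dev <- default_device_library()
  for (lib in list(lib4, lib2)) {
    spec <- lib$p1
    spec$device <- dev$d02
    spec$device$lead_curve <- NULL
    r <- render_attenuation_map(spec)
    poly <- synthmv:::place_device(spec)
    area_true <- synthmv:::polygon_area(poly)
    area_mask <- sum(r$device_mask[, , 1]) * spec$pixel_spacing^2
    # agreement within one perimeter-voxel band
    perim <- sum(sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), ])^2)))
    expect_lt(abs(area_mask - area_true), perim * spec$pixel_spacing)
  }
})

test_that("invalid phantom and device specifications are rejected", {
  expect_error(phantom_spec(body_axes = c(-1, 50)), "positive")
  expect_error(phantom_spec(base_intensities = c(air = 0, lung = -700,
                                                 soft = 40, bone = 700)),
               "ordered")
  expect_error(device_spec(rbind(c(0, 0), c(1, 1))), "vertices")
  expect_error(device_spec(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersecting")
  expect_error(device_spec(rbind(c(0, 0), c(10, 0), c(5, 8)), density_hu = 1500),
               "2000")
  # a device placed outside the grid errors with the offending geometry
  fx <- fixture_render()
  spec <- fx$spec
  spec$device_center <- c(-300, 0)
  expect_error(render_attenuation_map(spec), "outside")
})

test_that("the device library has ten simple devices and phantoms four geometries", {
  dev <- default_device_library()
  expect_length(dev, 10L)
  expect_true(all(vapply(dev, function(d) d$density_hu >= 2000, logical(1))))
  expect_length(default_phantom_library(), 4L)
})
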