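test_that("intensity clipping follows the kV and MV windows and is idempotent", {
  v <- image_volume(matrix(c(-2000, -1000, 0, 500, 3000, 2500), 2, 3),
                    spacing = c(1, 1, 1))
  kv <- clip_intensities(v, -1000, 2000)
  expect_equal(max(kv$data), 2000)   # a 3000 HU voxel clips to 2000
  expect_equal(min(kv$data), -1000)
  mv <- clip_intensities(v, -1000, 400)
  expect_equal(mv$data[2, 2, 1], 400)   # a 500 HU voxel clips to 400
  inside <- image_volume(matrix(c(0, 100), 1, 2))
  expect_equal(clip_intensities(inside, -1000, 2000)$data, inside$data)
  expect_identical(clip_intensities(kv, -1000, 2000)$data, kv$data)
  expect_error(clip_intensities(v, 10, 10), "lo < hi")
})

test_that("body mask matches the rasterized body on a noiseless MV slice", {
  fx <- fixture_render()
  mv <- simulate_mv_slice(fx$r$image, 0, 1)
  bm <- compute_body_mask(mv, -400)
  body <- fx$r$body_mask
  # agreement within a one-voxel boundary band
  disagree <- which(bm$mask[, , 1] != body[, , 1], arr.ind = TRUE)
  if (nrow(disagree) > 0) {
    surf <- which(body[, , 1] & !EBImage::erode(body[, , 1] * 1,
                                                EBImage::makeBrush(3, "box")),
                  arr.ind = TRUE)
    for (r in seq_len(nrow(disagree))) {
      dmin <- min(sqrt(rowSums(sweep(surf, 2, disagree[r, ])^2)))
      expect_lte(dmin, sqrt(2))
    }
  }
  expect_gt(sum(bm$mask), 0.8 * sum(body))

  # the mask ignores the device (it lies inside the body)
  spec_nd <- fx$spec
  spec_nd$device <- NULL
  mv_nd <- simulate_mv_slice(render_attenuation_map(spec_nd)$image, 0, 1)
  bm_nd <- compute_body_mask(mv_nd, -400)
  expect_identical(bm$mask, bm_nd$mask)

  air <- image_volume(array(-1000, c(8, 8, 1)))
  expect_error(compute_body_mask(air, -400), "threshold")
})

test_that("overlap cropping intersects validity masks into one common box", {
  fx <- fixture_render()
  v <- fx$r$image
  ident <- list(v, v)
  cr <- crop_to_overlap(ident)
  expect_identical(dim(cr[[1]]$data), dim(v$data))

  shifted <- resample(v, rigid_transform(0, c(32 * v$spacing[1], 0),
                                         volume_center(v)))
  cr2 <- crop_to_overlap(list(v, shifted))
  # brute-force voxel intersection box
  inter <- synthmv:::volume_validity(v) & synthmv:::volume_validity(shifted)
  idx <- which(inter, arr.ind = TRUE)
  expect_identical(dim(cr2[[1]]$data),
                   c(diff(range(idx[, 1])) + 1L, diff(range(idx[, 2])) + 1L,
                     diff(range(idx[, 3])) + 1L))
  expect_identical(dim(cr2[[1]]$data), dim(cr2[[2]]$data))

  gone <- resample(v, rigid_transform(0, c(1e5, 0), volume_center(v)))
  expect_error(crop_to_overlap(list(v, gone)), "empty")
})

test_that("network normalization maps the window onto [-1, 1] and inverts", {
  v <- image_volume(matrix(c(-1000, 500, 2000), 1, 3))
  nm <- normalize_for_network(v, -1000, 2000)
  expect_equal(as.vector(nm$data), c(-1, 0, 1))
  back <- denormalize_from_network(nm, -1000, 2000)
  expect_equal(back$data, v$data, tolerance = 1e-4)
})

test_that("patch extraction restricts centres to the body and cuts pairs jointly", {
  cases <- fixture_cases()
  cs <- cases[[1]]
  x <- normalize_for_network(clip_intensities(cs$kv_cbct, -1000, 2000), -1000, 2000)
  y <- normalize_for_network(clip_intensities(cs$mv_cbct, -1000, 400), -1000, 400)
  body <- compute_body_mask(cs$mv_cbct, -400)
  ps <- extract_patches(x, y, body, patch_size = 32L, n_patches = 20L, seed = 8)
  expect_equal(nrow(ps), 20L)
  for (k in seq_len(nrow(ps))) {
    expect_true(body$mask[ps$center_i[k], ps$center_j[k], ps$slice[k]])
    expect_identical(dim(ps$input[[k]]), c(32L, 32L))
    expect_identical(dim(ps$target[[k]]), c(32L, 32L))
    # paired-cut property: re-cutting at the stored corner reproduces both
    rr <- ps$row0[k]:(ps$row0[k] + 31L)
    cc <- ps$col0[k]:(ps$col0[k] + 31L)
    expect_identical(ps$input[[k]], x$data[rr, cc, ps$slice[k]])
    expect_identical(ps$target[[k]], y$data[rr, cc, ps$slice[k]])
  }
  expect_true(all(unlist(ps$input) >= -1 & unlist(ps$input) <= 1))
  ps2 <- extract_patches(x, y, body, patch_size = 32L, n_patches = 20L, seed = 8)
  expect_identical(ps$center_i, ps2$center_i)
  expect_identical(ps$input, ps2$input)
  expect_error(extract_patches(x, y, body, patch_size = 512L), "exceeds")
})

test_that("body-restricted patches contain at least as much body as unrestricted ones", {
  cases <- fixture_cases()
  cs <- cases[[2]]
  body <- compute_body_mask(cs$mv_cbct, -400)
  d <- dim(cs$mv_cbct$data)
  half <- 16L
  frac_at <- function(ci, cj, s) {
    r0 <- min(max(ci - half, 1L), d[1] - 32L + 1L)
    c0 <- min(max(cj - half, 1L), d[2] - 32L + 1L)
    mean(body$mask[r0:(r0 + 31L), c0:(c0 + 31L), s])
  }
  set.seed(12)
  centers <- which(body$mask, arr.ind = TRUE)
  restricted <- replicate(100, {
    p <- centers[sample.int(nrow(centers), 1), ]
    frac_at(p[1], p[2], p[3])
  })
  unrestricted <- replicate(100, {
    frac_at(sample.int(d[1], 1), sample.int(d[2], 1), sample.int(d[3], 1))
  })
  expect_gte(mean(restricted), mean(unrestricted))
})
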