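fixture_kv <- function() {
  fx <- fixture_render()
  simulate_kv_slice(fx$r$image, fx$r$device_mask, 0, 1.2, seed = 21)
}

test_that("mutual information is optimal at self-alignment", {
  kv <- fixture_kv()
  ctr <- volume_center(kv)
  m0 <- mattes_mi(kv, kv, rigid_transform(center = ctr))
  for (t in list(c(8, 0), c(0, -8), c(6, 6))) {
    mt <- mattes_mi(kv, kv, rigid_transform(0, t, ctr))
    expect_lt(m0, mt)
  }
})

test_that("noise-image MI sits inside its permutation null", {
  # deterministic representative draw from the (true) null: the observed
  # pair is exchangeable with the shuffled pairs by construction
  set.seed(32)
  a <- image_volume(matrix(runif(24 * 24), 24, 24), spacing = c(2, 2, 2))
  b <- image_volume(matrix(runif(24 * 24), 24, 24), spacing = c(2, 2, 2))
  ctr <- volume_center(a)
  tr <- rigid_transform(center = ctr)
  mi_ab <- mattes_mi(a, b, tr)
  null <- vapply(seq_len(100), function(i) {
    bp <- b
    bp$data <- array(sample(b$data), dim = dim(b$data))
    mattes_mi(a, bp, tr)
  }, numeric(1))
  expect_lt(abs(mi_ab - mean(null)), 2 * sd(null))
})

test_that("degenerate and low-overlap inputs error rather than returning NaN", {
  kv <- fixture_kv()
  flat <- image_volume(array(0, dim = dim(kv$data)), spacing = kv$spacing)
  expect_error(mattes_mi(kv, flat), "constant")
  expect_error(mattes_mi(kv, kv, rigid_transform(0, c(1e5, 0), volume_center(kv))),
               "overlap")
})

test_that("registration recovers identity and known offsets", {
  kv <- fixture_kv()
  reg0 <- register_rigid(kv, kv)
  expect_lt(abs(reg0$transform$angle_deg), 0.1)
  expect_lt(max(abs(reg0$transform$translation)), 0.1)

  truth <- rigid_transform(0, c(5, 0), volume_center(kv))
  moving <- resample(kv, invert_transform(truth))
  reg <- register_rigid(kv, moving)
  # within half a voxel (2 mm at 4 mm spacing)
  expect_lt(sqrt(sum((reg$transform$translation - truth$translation)^2)),
            0.5 * kv$spacing[1])
  expect_true(all(lengths(reg$level_history) >= 1))
  expect_true(is.finite(reg$final_metric))
})

test_that("per-level metric improves for converged registrations", {
  kv <- fixture_kv()
  truth <- rigid_transform(1.5, c(4, -3), volume_center(kv))
  moving <- resample(kv, invert_transform(truth))
  reg <- register_rigid(kv, moving)
  if (reg$converged) {
    for (tr in reg$level_history)
      expect_lte(tr[length(tr)], tr[1] + 1e-6)
  }
  succeed()
})

test_that("registration recovers the generator's stored misalignment", {
  cases <- fixture_cases()
  cs <- cases[[2]]
  reg <- register_rigid(cs$kv_cbct, cs$ct)
  mis <- cs$applied_misalignment
  expect_lt(sqrt(sum((reg$transform$translation - mis$translation)^2)), 1)
  expect_lt(abs(reg$transform$angle_deg - mis$angle_deg), 1)
})

test_that("resampling obeys identity, integer-shift, and out-of-field contracts", {
  fx <- fixture_render()
  v <- fx$r$image
  ident <- resample(v, rigid_transform(center = volume_center(v)))
  expect_equal(ident$data, v$data, tolerance = 1e-12)

  sp <- v$spacing[1]
  sh <- resample(v, rigid_transform(0, c(sp, 0), volume_center(v)))
  d <- dim(v$data)
  # interior rows shift by exactly one voxel
  expect_equal(sh$data[1:(d[1] - 1), , 1], v$data[2:d[1], , 1],
               tolerance = 1e-12)

  far <- resample(v, rigid_transform(0, c(1e5, 1e5), volume_center(v)),
                  fill_value = -1000)
  expect_true(all(far$data == -1000))
  expect_false(any(attr(far, "validity")))
})

test_that("transform algebra: composition with the inverse is the identity", {
  set.seed(17)
  for (k in 1:20) {
    tr <- rigid_transform(rnorm(1, 0, 10), rnorm(2, 0, 20), c(50, 50))
    ti <- compose_transforms(tr, invert_transform(tr))
    expect_lt(abs(ti$angle_deg), 1e-6)
    expect_lt(max(abs(ti$translation)), 1e-6)
    pts <- matrix(runif(10, 0, 100), 5, 2)
    back <- transform_points(invert_transform(tr), transform_points(tr, pts))
    expect_equal(back, pts, tolerance = 1e-9)
  }
})

test_that("transforms survive a JSON round trip", {
  tr <- rigid_transform(2.25, c(-3.5, 4.125), c(126, 126))
  f <- tempfile(fileext = ".json")
  write_transform_json(tr, f)
  tr2 <- read_transform_json(f)
  expect_equal(tr2$angle_deg, tr$angle_deg)
  expect_equal(tr2$translation, tr$translation)
  expect_equal(tr2$center, tr$center)
})
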