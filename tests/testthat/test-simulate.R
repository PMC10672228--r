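test_that("FBP reproduces the attenuation map within its discretization tolerance", {
  fx <- fixture_render()
  spec <- fx$spec
  spec$device <- NULL
  r <- render_attenuation_map(spec)
  rec180 <- simulate_kv_slice(r$image, NULL, noise_sd = 0, streak_strength = 0,
                              seed = 1, n_angles = 180L)
  rec360 <- simulate_kv_slice(r$image, NULL, noise_sd = 0, streak_strength = 0,
                              seed = 1, n_angles = 360L)
  mae180 <- mean(abs(rec180$data[, , 1] - r$image$data[, , 1]))
  mae360 <- mean(abs(rec360$data[, , 1] - r$image$data[, , 1]))
  # converged in angle: doubling the angular sampling changes the error
  # by little, so the 180-view error is within 25% of the converged error
  expect_lt(mae180, 1.25 * mae360)
})

test_that("streaks concentrate error around the device and spare distant lung", {
  fx <- fixture_render()
  r <- fx$r
  clean <- simulate_kv_slice(r$image, r$device_mask, 0, 0, seed = 4)
  streaked <- simulate_kv_slice(r$image, r$device_mask, 0, 1.2, seed = 4)
  sl <- r$image$data[, , 1]
  dmask <- r$device_mask[, , 1]
  idx <- which(dmask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  X <- matrix(seq_len(nrow(sl)), nrow(sl), ncol(sl))
  Y <- t(X)
  dist <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
  ann <- dist > 3 & dist < 10 & sl == 40
  err_streak <- mean(abs(streaked$data[, , 1] - sl)[ann])
  err_clean <- mean(abs(clean$data[, , 1] - sl)[ann])
  expect_gt(err_streak, err_clean)

  # locality: lung voxels far from the device see little of the streaks
  noise_sd <- 30
  noisy_clean <- simulate_kv_slice(r$image, r$device_mask, noise_sd, 0, seed = 4)
  noisy_streak <- simulate_kv_slice(r$image, r$device_mask, noise_sd, 1.2, seed = 4)
  lung_far <- sl == -700 & dist > 25
  delta <- abs(noisy_streak$data[, , 1] - noisy_clean$data[, , 1])
  expect_lt(median(delta[lung_far]), 3 * noise_sd)
})

test_that("kV simulation is deterministic per seed and validates inputs", {
  fx <- fixture_render()
  a <- simulate_kv_slice(fx$r$image, fx$r$device_mask, 25, 1.2, seed = 9)
  b <- simulate_kv_slice(fx$r$image, fx$r$device_mask, 25, 1.2, seed = 9)
  expect_identical(a$data, b$data)
  expect_error(simulate_kv_slice(fx$r$image, fx$r$device_mask, 25, -1),
               ">= 0")
  expect_error(simulate_kv_slice(fx$r$image, fx$r$device_mask[1:2, , ]),
               "congruent")
  expect_true(all(a$data >= -1000 & a$data <= 2000))
})

test_that("MV rendering is bounded, monotone, and recovers the device mask", {
  fx <- fixture_render()
  mv0 <- simulate_mv_slice(fx$r$image, noise_sd = 0, seed = 1)
  expect_true(all(mv0$data >= -1000 & mv0$data <= 400))
  # monotone map contract
  xs <- seq(-1100, 2100, by = 7)
  expect_true(all(diff(mv_intensity_map(xs)) >= 0))
  # thresholding the noiseless rendering at the soft/device midpoint
  # reproduces the device mask exactly
  expect_identical(mv0$data >= mv_device_threshold(), fx$r$device_mask)
})

test_that("device conspicuity is higher on MV than on kV at default settings", {
  design <- fixture_design(1)
  cs <- generate_study(design)[[1]]
  sl <- cs$mu_map$data[, , 1]
  dmask <- cs$device_mask$data[, , 1] > 0
  idx <- which(dmask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  X <- matrix(seq_len(nrow(sl)), nrow(sl), ncol(sl))
  Y <- t(X)
  dist <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
  ann <- dist > 3 & dist < 10 & sl == 40
  cnr <- function(img) abs(mean(img[dmask]) - mean(img[ann])) / sd(img[ann])
  expect_gt(cnr(cs$mv_cbct$data[, , 1]), cnr(cs$kv_cbct$data[, , 1]))
})

test_that("study generation matches its design and is reproducible", {
  cases <- fixture_cases()
  expect_length(cases, 6L)
  ids <- vapply(cases, function(c) c$case_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  cs <- cases[[1]]
  expect_identical(dim(cs$kv_cbct$data), dim(cs$mv_cbct$data))
  expect_identical(dim(cs$kv_cbct$data), dim(cs$device_mask$data))
  expect_gt(sum(cs$device_mask$data), 0)

  again <- generate_study(fixture_design())
  expect_identical(cases[[3]]$kv_cbct$data, again[[3]]$kv_cbct$data)
  expect_identical(cases[[3]]$ct$data, again[[3]]$ct$data)

  zero <- generate_study(fixture_design(
    n = 2, misalignment_sd = list(translation_mm = 0, rotation_deg = 0)))
  for (cs in zero) {
    expect_equal(cs$applied_misalignment$angle_deg, 0)
    expect_equal(cs$applied_misalignment$translation, c(0, 0))
  }

  bad <- study_design(combinations = tibble::tibble(device_id = "nope",
                                                    phantom_id = "p1"))
  expect_error(generate_study(bad), "nope")
})

test_that("dataset splitting is a seeded disjoint partition with rounded sizes", {
  cases <- as.list(letters[1:35])
  sp <- split_dataset(cases, 0.8, seed = 3)
  expect_length(sp$train, 28L)
  expect_length(sp$test, 7L)
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), letters[1:35])
  expect_length(intersect(unlist(sp$train), unlist(sp$test)), 0L)
  sp2 <- split_dataset(cases, 0.8, seed = 3)
  expect_identical(unlist(sp$train), unlist(sp2$train))
  sp3 <- split_dataset(cases, 0.8, seed = 4)
  expect_false(identical(unlist(sp$train), unlist(sp3$train)))
  expect_error(split_dataset(cases[1], 0.8), "at least 2")
  expect_error(split_dataset(cases, 1.2), "train_fraction")
})
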