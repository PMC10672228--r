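test_that("Dice handles identity, disjoint, partial overlap, and empty input", {
  sp <- c(1, 1, 1)
  a <- array(FALSE, c(6, 6, 1)); a[2:3, 2:3, 1] <- TRUE
  expect_equal(dice(contour_mask(a, sp), contour_mask(a, sp)), 1)
  b <- array(FALSE, c(6, 6, 1)); b[5:6, 5:6, 1] <- TRUE
  expect_equal(dice(contour_mask(a, sp), contour_mask(b, sp)), 0)
  cpartial <- array(FALSE, c(6, 6, 1)); cpartial[2:3, 3:4, 1] <- TRUE
  # |A| = |B| = 4, |A intersect B| = 2 -> 2*2/(4+4)
  expect_equal(dice(contour_mask(a, sp), contour_mask(cpartial, sp)), 0.5)
  e <- array(FALSE, c(6, 6, 1))
  expect_error(dice(contour_mask(e, sp), contour_mask(e, sp)), "empty")
})

test_that("surface distances match simple geometry", {
  a <- array(FALSE, c(8, 8, 1)); a[2, 2, 1] <- TRUE
  b <- array(FALSE, c(8, 8, 1)); b[2, 5, 1] <- TRUE
  d <- surface_distances(contour_mask(a, c(1, 1, 1)), contour_mask(b, c(1, 1, 1)))
  expect_equal(d$d_ab, 3)
  expect_equal(d$d_ba, 3)
  same <- surface_distances(contour_mask(a, c(1, 1, 1)), contour_mask(a, c(1, 1, 1)))
  expect_true(all(same$d_ab == 0) && all(same$d_ba == 0))
  expect_error(surface_distances(contour_mask(a), contour_mask(array(FALSE, c(8, 8, 1)))),
               "non-empty")
})

test_that("the shifted-square case matches the exhaustive all-pairs oracle", {
  a <- array(FALSE, c(16, 16, 1)); a[4:13, 4:13, 1] <- TRUE
  b <- array(FALSE, c(16, 16, 1)); b[6:15, 4:13, 1] <- TRUE
  sp <- c(1, 1, 1)
  d <- surface_distances(contour_mask(a, sp), contour_mask(b, sp))
  br <- brute_metrics(a, b, sp)
  expect_equal(sort(d$d_ab), sort(brute_directed(brute_surface_pts(a, sp),
                                                 brute_surface_pts(b, sp))))
  expect_equal(surface_dice(contour_mask(a, sp), contour_mask(b, sp), 1), br$sdsc)
  expect_equal(hd95(contour_mask(a, sp), contour_mask(b, sp)), br$hd95)
  expect_equal(msd(contour_mask(a, sp), contour_mask(b, sp)), br$msd)
})

test_that("surface Dice is 1 for identical masks and 0 beyond tolerance", {
  a <- array(FALSE, c(10, 10, 1)); a[2:4, 2:4, 1] <- TRUE
  expect_equal(surface_dice(contour_mask(a), contour_mask(a), 0.5), 1)
  b <- array(FALSE, c(10, 10, 1)); b[8:9, 8:9, 1] <- TRUE
  expect_equal(surface_dice(contour_mask(a), contour_mask(b), 1), 0)
})

test_that("hd95 follows the linear-interpolation percentile rule", {
  # frozen oracle: pooled multiset {0 x 19, 10}; h = 0.95*(20-1)+1 = 19.05
  # -> x[19] + 0.05 * (x[20] - x[19]) = 0.5
  pooled <- c(rep(0, 19), 10)
  expect_equal(unname(quantile(pooled, 0.95, type = 7)), 0.5)
  a <- array(FALSE, c(6, 6, 1)); a[3, 3, 1] <- TRUE
  expect_equal(hd95(contour_mask(a), contour_mask(a)), 0)
  b <- array(FALSE, c(6, 6, 1)); b[3, 5, 1] <- TRUE
  expect_equal(hd95(contour_mask(a), contour_mask(b)), 2)  # all distances = c
})

test_that("msd is the directed mean by default with a symmetric option", {
  a <- array(FALSE, c(8, 8, 1)); a[2, 2, 1] <- TRUE
  b <- array(FALSE, c(8, 8, 1)); b[5, 2, 1] <- TRUE
  expect_equal(msd(contour_mask(a), contour_mask(b)), 3)
  big <- array(FALSE, c(8, 8, 1)); big[2:6, 2:6, 1] <- TRUE
  m_dir <- msd(contour_mask(a), contour_mask(big))
  m_sym <- msd(contour_mask(a), contour_mask(big), symmetric = TRUE)
  expect_false(isTRUE(all.equal(m_dir, m_sym)))
})

test_that("metric symmetry and monotone degradation hold", {
  set.seed(91)
  a <- rand_mask(); b <- rand_mask()
  ca <- contour_mask(a); cb <- contour_mask(b)
  expect_equal(dice(ca, cb), dice(cb, ca))
  expect_equal(surface_dice(ca, cb, 1), surface_dice(cb, ca, 1))
  expect_equal(hd95(ca, cb), hd95(cb, ca))
  # translate a mask by growing offsets: DSC non-increasing, distances growing
  base <- array(FALSE, c(20, 20, 1)); base[5:10, 5:10, 1] <- TRUE
  ds <- hs <- c()
  for (off in 0:4) {
    sh <- array(FALSE, c(20, 20, 1)); sh[(5 + off):(10 + off), 5:10, 1] <- TRUE
    ds <- c(ds, dice(contour_mask(base), contour_mask(sh)))
    hs <- c(hs, hd95(contour_mask(base), contour_mask(sh)))
  }
  expect_true(all(diff(ds) <= 1e-12))
  expect_true(all(diff(hs) >= -1e-12))
})

test_that("rank-sum test is exact by enumeration and symmetric", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1)       # 2/20 rank assignments are as extreme
  expect_match(rs$method, "exact")
  rs2 <- rank_sum_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rs2$p_value, rs$p_value)
  same <- rank_sum_test(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("rank-sum p-values agree with the reference implementation", {
  set.seed(5)
  # exact regime, no ties
  for (k in 1:5) {
    x <- sample(100, 5); y <- sample(200, 6) + 0.5
    ours <- rank_sum_test(x, y)$p_value
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # large-sample normal approximation with ties
  x <- c(rnorm(20), 1, 1, 2); y <- c(rnorm(20, 0.5), 1, 2, 2)
  ours <- rank_sum_test(x, y)$p_value
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-9)
})
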