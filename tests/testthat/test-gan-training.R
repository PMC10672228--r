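tiny_gen <- function(bc = 8L) generator_config(base_channels = bc,
                                               n_residual_blocks = 1L)
tiny_disc <- function(bc = 8L) discriminator_config(base_channels = bc)

test_that("cGAN fits an identity task to low paired error", {
  set.seed(7)
  xs <- lapply(1:48, function(i) smooth_field())
  pairs <- tibble::tibble(input = xs, target = xs)
  tr <- train_cgan(pairs, tiny_gen(), tiny_disc(),
                   train_config(epochs = 84L, batch_size = 8L,
                                learning_rate = 1e-3, beta1 = 0.9, seed = 1))
  expect_lt(mean(utils::tail(tr$trace$g_l1, 10)), 0.05)
  expect_true(all(is.finite(tr$trace$g_total)))
})

test_that("without the paired term and with a frozen discriminator the L1 error does not converge", {
  set.seed(19)
  drops <- vapply(1:5, function(sd) {
    xs <- lapply(1:16, function(i) smooth_field())
    ys <- lapply(1:16, function(i) smooth_field())
    tr <- train_cgan(tibble::tibble(input = xs, target = ys),
                     tiny_gen(4L), tiny_disc(4L),
                     train_config(epochs = 15L, batch_size = 8L,
                                  learning_rate = 1e-3, beta1 = 0.9,
                                  lambda_l1 = 0, freeze_d = TRUE, seed = sd))
    first <- mean(utils::head(tr$trace$g_l1, 5))
    last <- mean(utils::tail(tr$trace$g_l1, 5))
    (first - last) / first
  }, numeric(1))
  # no systematic decrease toward the paired target (a converging paired
  # run drops by well over half in the same budget)
  expect_lt(mean(drops), 0.2)
})

test_that("training is deterministic and checkpoints reload bit-identically", {
  set.seed(23)
  xs <- lapply(1:16, function(i) smooth_field())
  ys <- lapply(1:16, function(i) smooth_field())
  pairs <- tibble::tibble(input = xs, target = ys)
  cfg <- train_config(epochs = 5L, batch_size = 8L, seed = 3)
  t1 <- train_cgan(pairs, tiny_gen(), tiny_disc(), cfg)
  t2 <- train_cgan(pairs, tiny_gen(), tiny_disc(), cfg)
  expect_identical(synthmv:::net_snapshot(t1$generator),
                   synthmv:::net_snapshot(t2$generator))
  expect_identical(t1$trace, t2$trace)

  f <- tempfile(fileext = ".rds")
  save_translator(t1, f)
  t3 <- load_translator(f)
  img <- image_volume(matrix(runif(64 * 64, -1000, 2000), 64, 64),
                      spacing = c(4, 4, 4))
  expect_identical(translate(t1, img)$data, translate(t3, img)$data)
})

test_that("cycleGAN reduces cycle consistency on matched domains", {
  set.seed(7)
  xs <- lapply(1:32, function(i) smooth_field())
  res <- train_cyclegan(xs, xs, tiny_gen(), tiny_disc(),
                        train_config(epochs = 75L, batch_size = 8L,
                                     learning_rate = 1e-3, beta1 = 0.9,
                                     seed = 1))
  # mean per-direction cycle error over the last 10 steps
  expect_lt(mean(utils::tail(res$trace$cycle_raw, 10)) / 2, 0.1)
  expect_s3_class(res$ab, "trained_translator")
  expect_s3_class(res$ba, "trained_translator")
})

test_that("a zero cycle weight removes the cycle term from the loss trace exactly", {
  set.seed(29)
  xs <- lapply(1:8, function(i) smooth_field())
  res <- train_cyclegan(xs, xs, tiny_gen(4L), tiny_disc(4L),
                        train_config(epochs = 2L, batch_size = 8L,
                                     lambda_cycle = 0, seed = 1))
  expect_true(all(res$trace$cycle_term == 0))
  expect_error(train_config(lambda_cycle = -1), "non-negative")
  expect_error(train_cyclegan(list(), xs), "non-empty")
})

test_that("inference copies grid metadata, bounds output to the MV window, and is deterministic", {
  set.seed(23)
  xs <- lapply(1:8, function(i) smooth_field())
  pairs <- tibble::tibble(input = xs, target = xs)
  tr <- train_cgan(pairs, tiny_gen(4L), tiny_disc(4L),
                   train_config(epochs = 2L, batch_size = 8L, seed = 3))
  img <- image_volume(array(runif(66 * 70 * 2, -1200, 2500), c(66, 70, 2)),
                      spacing = c(4, 4, 2), modality = "kv_cbct")
  s1 <- translate(tr, img)
  s2 <- translate(tr, img)
  expect_identical(dim(s1$data), dim(img$data))   # reflect-pad and crop back
  expect_identical(s1$spacing, img$spacing)
  expect_true(all(s1$data >= -1000 & s1$data <= 400))
  expect_identical(s1$data, s2$data)
})
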