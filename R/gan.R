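#' Training configuration for the translation models
#'
#' Defaults follow the conditional-GAN / cycleGAN lineage: least-squares
#' adversarial loss, Adam (learning rate 2e-4, beta1 0.5), L1 weight 100
#' (paired route) and cycle-consistency weight 10 (unpaired route). The seed
#' fixes weight initialization and batch order; training is deterministic
#' for a fixed seed.
#'
#' @param epochs passes over the patch set.
#' @param batch_size patches per step.
#' @param learning_rate Adam step size.
#' @param lambda_l1 paired L1 weight (cGAN).
#' @param lambda_cycle cycle-consistency weight (cycleGAN).
#' @param beta1 Adam first-moment decay.
#' @param seed integer.
#' @param checkpoint_every record a weight snapshot every this many steps
#'   (0 = only final).
#' @param freeze_d keep the discriminator at its initialization (no updates);
#'   used for adversarial-only ablation studies.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 5L, batch_size = 4L, learning_rate = 2e-4,
                         lambda_l1 = 100, lambda_cycle = 10, beta1 = 0.5,
                         seed = 1L, checkpoint_every = 0L, freeze_d = FALSE) {
  if (lambda_l1 < 0 || lambda_cycle < 0)
    stop_synthmv("loss weights must be non-negative")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adversarial_loss = "lsgan",
                 lambda_l1 = lambda_l1, lambda_cycle = lambda_cycle,
                 beta1 = beta1, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 freeze_d = isTRUE(freeze_d)),
            class = "train_config")
}

# stack a list of matrices into an (H, W, 1, N) tensor
patches_to_tensor <- function(patches) {
  h <- nrow(patches[[1]]); w <- ncol(patches[[1]])
  array(unlist(patches, use.names = FALSE), dim = c(h, w, 1L, length(patches)))
}

lsgan_grad <- function(d_out, target) 2 * (d_out - target) / length(d_out)

new_translator <- function(gen, gen_cfg, route, model, norm_in, norm_out,
                           trace) {
  structure(list(generator = gen, gen_cfg = gen_cfg, route = route,
                 model = model, norm_in = norm_in, norm_out = norm_out,
                 trace = trace),
            class = "trained_translator")
}

#' @export
print.trained_translator <- function(x, ...) {
  cat(sprintf("<trained_translator> %s / %s, %d generator parameters\n",
              x$model, x$route, param_count(x$generator)))
  invisible(x)
}

#' Train a paired conditional GAN translator
#'
#' Alternating discriminator/generator updates with least-squares
#' adversarial loss; the generator loss adds `lambda_l1` times the mean
#' absolute error to the paired target patch. Fully seeded and
#' deterministic; aborts with the last finite state if the loss diverges.
#'
#' @param pairs tibble from [extract_patches()] (columns `input`, `target`,
#'   normalized patches), or a list with `input`/`target` matrix lists.
#' @param gen_cfg a [generator_config()].
#' @param disc_cfg a [discriminator_config()].
#' @param tcfg a [train_config()].
#' @param route label (`"ct2mv"` or `"kv2mv"`).
#' @param norm_in,norm_out HU windows the patches were normalized with.
#' @return A `trained_translator` with a per-step loss trace.
#' @export
train_cgan <- function(pairs, gen_cfg = generator_config(),
                       disc_cfg = discriminator_config(),
                       tcfg = train_config(), route = "kv2mv",
                       norm_in = kv_clip_range(), norm_out = mv_clip_range()) {
  xs <- pairs$input; ys <- pairs$target
  if (length(xs) == 0) stop_synthmv("empty training set")
  trace <- list()
  res <- with_seed(tcfg$seed, {
    G <- build_generator(gen_cfg)
    D <- build_discriminator(disc_cfg)
    adam_init(G); adam_init(D)
    n <- length(xs)
    step <- 0L
    ok <- TRUE
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = tcfg$batch_size)) {
        idx <- ord[b0:min(b0 + tcfg$batch_size - 1L, n)]
        x <- patches_to_tensor(xs[idx])
        y <- patches_to_tensor(ys[idx])
        step <- step + 1L

        # discriminator: 0.5 [ (D(y) - 1)^2 + D(G(x))^2 ]
        fake <- generator_forward(G, x)
        zero_grads(D)
        dr <- net_forward(D, y)
        net_backward(D, 0.5 * lsgan_grad(dr, 1))
        df <- net_forward(D, fake)
        net_backward(D, 0.5 * lsgan_grad(df, 0))
        d_loss <- 0.5 * (mean((dr - 1)^2) + mean(df^2))
        if (!tcfg$freeze_d) adam_step(D, tcfg$learning_rate, step, tcfg$beta1)

        # generator: (D(G(x)) - 1)^2 + lambda_l1 * |G(x) - y|
        zero_grads(G)
        fake <- generator_forward(G, x)
        df2 <- net_forward(D, fake)
        zero_grads(D)  # input gradient only; discard its parameter grads
        g_in <- net_backward(D, lsgan_grad(df2, 1), need_input_grad = TRUE)
        l1 <- mean(abs(fake - y))
        g_l1 <- tcfg$lambda_l1 * sign(fake - y) / length(fake)
        net_backward(G, g_in + g_l1)
        adam_step(G, tcfg$learning_rate, step, tcfg$beta1)

        g_adv <- mean((df2 - 1)^2)
        if (!all(is.finite(c(d_loss, g_adv, l1)))) {
          ok <- FALSE
          break
        }
        trace[[step]] <- tibble::tibble(step = step, epoch = ep,
                                        d_loss = d_loss, g_adv = g_adv,
                                        g_l1 = l1,
                                        g_total = g_adv + tcfg$lambda_l1 * l1)
      }
      if (!ok) break
    }
    list(G = G, trace = dplyr::bind_rows(trace), ok = ok)
  })
  if (!res$ok)
    warning("non-finite loss encountered; returning last finite state")
  new_translator(res$G, gen_cfg, route, "cgan", norm_in, norm_out, res$trace)
}

#' Train an (unpaired-capable) cycleGAN translator pair
#'
#' Two generators (A to B and B to A) and two patch discriminators, with
#' least-squares adversarial losses in both domains plus
#' `lambda_cycle * (|F(G(a)) - a| + |G(F(b)) - b|)`. No pairing between the
#' two patch sets is required or used.
#'
#' @param domain_a,domain_b lists of normalized patch matrices (domain A:
#'   kV input; domain B: MV target).
#' @inheritParams train_cgan
#' @return list with `ab` and `ba` `trained_translator`s and the shared
#'   loss `trace`.
#' @export
train_cyclegan <- function(domain_a, domain_b, gen_cfg = generator_config(),
                           disc_cfg = discriminator_config(),
                           tcfg = train_config(), route = "kv2mv",
                           norm_in = kv_clip_range(), norm_out = mv_clip_range()) {
  if (!length(domain_a) || !length(domain_b))
    stop_synthmv("both domains must be non-empty")
  trace <- list()
  res <- with_seed(tcfg$seed, {
    G <- build_generator(gen_cfg)   # A -> B
    F_ <- build_generator(gen_cfg)  # B -> A
    DB <- build_discriminator(disc_cfg)
    DA <- build_discriminator(disc_cfg)
    for (nt in list(G, F_, DB, DA)) adam_init(nt)
    na <- length(domain_a); nb <- length(domain_b)
    nsteps_ep <- ceiling(max(na, nb) / tcfg$batch_size)
    step <- 0L
    ok <- TRUE
    for (ep in seq_len(tcfg$epochs)) {
      orda <- sample.int(na); ordb <- sample.int(nb)
      for (bs in seq_len(nsteps_ep)) {
        ia <- orda[((bs - 1L) * tcfg$batch_size + seq_len(tcfg$batch_size) - 1L) %% na + 1L]
        ib <- ordb[((bs - 1L) * tcfg$batch_size + seq_len(tcfg$batch_size) - 1L) %% nb + 1L]
        a <- patches_to_tensor(domain_a[ia])
        b <- patches_to_tensor(domain_b[ib])
        step <- step + 1L

        # ---- generator updates ----
        zero_grads(G); zero_grads(F_)
        # branch 1: a -> G -> fake_b -> F -> rec_a
        fake_b <- generator_forward(G, a)
        rec_a <- generator_forward(F_, fake_b)
        cyc_a <- mean(abs(rec_a - a))
        g_to_G <- 0 * fake_b
        if (tcfg$lambda_cycle > 0) {
          gca <- tcfg$lambda_cycle * sign(rec_a - a) / length(rec_a)
          g_to_G <- g_to_G + net_backward(F_, gca, need_input_grad = TRUE)
        }
        db_f <- net_forward(DB, fake_b)
        zero_grads(DB)
        g_to_G <- g_to_G + net_backward(DB, lsgan_grad(db_f, 1),
                                        need_input_grad = TRUE)
        adv_g <- mean((db_f - 1)^2)
        net_backward(G, g_to_G)
        # branch 2: b -> F -> fake_a -> G -> rec_b
        fake_a <- generator_forward(F_, b)
        rec_b <- generator_forward(G, fake_a)
        cyc_b <- mean(abs(rec_b - b))
        g_to_F <- 0 * fake_a
        if (tcfg$lambda_cycle > 0) {
          gcb <- tcfg$lambda_cycle * sign(rec_b - b) / length(rec_b)
          g_to_F <- g_to_F + net_backward(G, gcb, need_input_grad = TRUE)
        }
        da_f <- net_forward(DA, fake_a)
        zero_grads(DA)
        g_to_F <- g_to_F + net_backward(DA, lsgan_grad(da_f, 1),
                                        need_input_grad = TRUE)
        adv_f <- mean((da_f - 1)^2)
        net_backward(F_, g_to_F)
        adam_step(G, tcfg$learning_rate, step, tcfg$beta1)
        adam_step(F_, tcfg$learning_rate, step, tcfg$beta1)

        # ---- discriminator updates (fakes detached) ----
        zero_grads(DB)
        dbr <- net_forward(DB, b)
        net_backward(DB, 0.5 * lsgan_grad(dbr, 1))
        dbf <- net_forward(DB, fake_b)
        net_backward(DB, 0.5 * lsgan_grad(dbf, 0))
        adam_step(DB, tcfg$learning_rate, step, tcfg$beta1)
        zero_grads(DA)
        dar <- net_forward(DA, a)
        net_backward(DA, 0.5 * lsgan_grad(dar, 1))
        daf <- net_forward(DA, fake_a)
        net_backward(DA, 0.5 * lsgan_grad(daf, 0))
        adam_step(DA, tcfg$learning_rate, step, tcfg$beta1)

        cyc_term <- tcfg$lambda_cycle * (cyc_a + cyc_b)
        vals <- c(adv_g, adv_f, cyc_term)
        if (!all(is.finite(vals))) { ok <- FALSE; break }
        trace[[step]] <- tibble::tibble(
          step = step, epoch = ep, adv_ab = adv_g, adv_ba = adv_f,
          cycle_raw = cyc_a + cyc_b, cycle_term = cyc_term,
          d_b = 0.5 * (mean((dbr - 1)^2) + mean(dbf^2)),
          d_a = 0.5 * (mean((dar - 1)^2) + mean(daf^2)))
      }
      if (!ok) break
    }
    list(G = G, F_ = F_, trace = dplyr::bind_rows(trace), ok = ok)
  })
  if (!res$ok)
    warning("non-finite loss encountered; returning last finite state")
  list(ab = new_translator(res$G, gen_cfg, route, "cyclegan", norm_in,
                           norm_out, res$trace),
       ba = new_translator(res$F_, gen_cfg, paste0(route, "_reverse"),
                           "cyclegan", norm_out, norm_in, res$trace),
       trace = res$trace)
}

#' Translate a kV-domain volume into a synthetic MV volume
#'
#' Slice-wise full-frame inference: the input is clipped and normalized
#' with the translator's stored constants, reflect-padded to the
#' generator's divisibility requirement if necessary, passed through the
#' generator, cropped back, and denormalized onto the MV HU range.
#' Inference is deterministic.
#'
#' @param translator a `trained_translator`.
#' @param image an [image_volume()] on the kV HU scale.
#' @return [image_volume()] of synthetic MV intensities within the MV
#'   clip window, grid metadata copied from the input.
#' @export
translate <- function(translator, image) {
  stopifnot(inherits(translator, "trained_translator"), is_image_volume(image))
  ni <- translator$norm_in; no <- translator$norm_out
  x <- normalize_for_network(clip_intensities(image, ni[["lo"]], ni[["hi"]]),
                             ni[["lo"]], ni[["hi"]])
  d <- dim(x$data)
  dv <- attr(translator$generator, "divisor") %||% 4L
  ph <- (dv - d[1] %% dv) %% dv
  pw <- (dv - d[2] %% dv) %% dv
  arr <- x$data
  if (ph > 0 || pw > 0) {
    # reflect-pad at the high edge, crop back after inference
    arr2 <- array(0, dim = c(d[1] + ph, d[2] + pw, d[3]))
    for (s in seq_len(d[3])) {
      sl <- arr[, , s]
      if (ph > 0) sl <- rbind(sl, sl[nrow(sl) - seq_len(ph) + 1L, , drop = FALSE])
      if (pw > 0) sl <- cbind(sl, sl[, ncol(sl) - seq_len(pw) + 1L, drop = FALSE])
      arr2[, , s] <- sl
    }
    arr <- arr2
  }
  xt <- array(arr, dim = c(dim(arr)[1], dim(arr)[2], 1L, d[3]))
  yt <- generator_forward(translator$generator, xt)
  out <- array(yt, dim = dim(arr))[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  hu <- denormalize_from_network(out, no[["lo"]], no[["hi"]])
  image_volume(hu, spacing = image$spacing, origin = image$origin,
               modality = "smv_cbct")
}

#' Save / load a trained translator
#'
#' The checkpoint stores the generator weights, full configuration,
#' normalization constants and route label; reloading reproduces forward
#' outputs bit-identically.
#'
#' @param translator a `trained_translator`.
#' @param path checkpoint path (`.rds`).
#' @return `path` / the reloaded `trained_translator`.
#' @export
save_translator <- function(translator, path) {
  saveRDS(list(weights = net_snapshot(translator$generator),
               gen_cfg = translator$gen_cfg, route = translator$route,
               model = translator$model, norm_in = translator$norm_in,
               norm_out = translator$norm_out, trace = translator$trace),
          path)
  invisible(path)
}

#' @rdname save_translator
#' @export
load_translator <- function(path) {
  x <- readRDS(path)
  gen <- with_seed(0L, build_generator(x$gen_cfg))
  net_restore(gen, x$weights)
  new_translator(gen, x$gen_cfg, x$route, x$model, x$norm_in, x$norm_out,
                 x$trace)
}
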