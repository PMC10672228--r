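# Compact 2D convolutional network engine backing the translation models.
# Tensors are R arrays laid out (H, W, C, N); convolution arithmetic runs in
# C++ (see src/conv_ops.cpp), elementwise layers stay in vectorized R.
# Layers are environments so parameter/gradient state mutates in place.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

init_weight <- function(kh, kw, cin, cout, sd = 0.02) {
  array(rnorm(kh * kw * cin * cout, 0, sd), dim = c(kh, kw, cin, cout))
}

layer_conv <- function(cin, cout, k, stride = 1, pad = 0) {
  new_layer("conv", w = init_weight(k, k, cin, cout), b = numeric(cout),
            stride = as.integer(stride), pad = as.integer(pad))
}

# transposed convolution; weights are stored in the adjoint (conv) view:
# (k, k, cout, cin) so the forward pass is the conv data-gradient kernel
layer_tconv <- function(cin, cout, k, stride = 1, pad = 0, out_pad = 0) {
  new_layer("tconv", w = init_weight(k, k, cout, cin), b = numeric(cout),
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), out_pad = as.integer(out_pad))
}

layer_instnorm <- function(ch, eps = 1e-5) {
  new_layer("instnorm", gamma = rep(1, ch), beta = numeric(ch),
            ch = as.integer(ch), eps = eps)
}

layer_lrelu <- function(slope = 0.2) new_layer("lrelu", slope = slope)
layer_tanh <- function() new_layer("tanh")

layer_resblock <- function(ch, slope = 0.2) {
  new_layer("resblock", sub = list(
    layer_conv(ch, ch, 3, 1, 1), layer_instnorm(ch), layer_lrelu(slope),
    layer_conv(ch, ch, 3, 1, 1), layer_instnorm(ch)))
}

layer_forward <- function(l, x) {
  switch(l$type,
    conv = {
      l$x <- x
      cpp_conv2d_forward(x, l$w, l$b, l$stride, l$pad)
    },
    tconv = {
      l$x <- x
      d <- dim(x)
      Ht <- l$stride * (d[1] - 1L) - 2L * l$pad + l$k + l$out_pad
      Wt <- l$stride * (d[2] - 1L) - 2L * l$pad + l$k + l$out_pad
      y <- cpp_conv2d_bwd_data(x, l$w, l$stride, l$pad, Ht, Wt)
      dy <- dim(y)
      y + array(rep(rep(l$b, each = dy[1] * dy[2]), dy[4]), dim = dy)
    },
    instnorm = {
      d <- dim(x)
      hw <- d[1] * d[2]
      m <- matrix(x, hw)
      mu <- colMeans(m)
      v <- colMeans(m * m) - mu^2
      istd <- 1 / sqrt(v + l$eps)
      xh <- sweep(sweep(m, 2, mu), 2, istd, `*`)
      colc <- rep_len(seq_len(l$ch), ncol(m))
      y <- sweep(sweep(xh, 2, l$gamma[colc], `*`), 2, l$beta[colc], `+`)
      l$xh <- xh; l$istd <- istd; l$dims <- d; l$colc <- colc
      array(y, dim = d)
    },
    lrelu = {
      pos <- x >= 0
      l$pos <- pos
      x * (pos + l$slope * !pos)
    },
    tanh = {
      y <- tanh(x)
      l$y <- y
      y
    },
    resblock = {
      h <- x
      for (s in l$sub) h <- layer_forward(s, h)
      x + h
    },
    stop_synthmv("unknown layer type %s", l$type))
}

layer_backward <- function(l, g, need_gx = TRUE) {
  switch(l$type,
    conv = {
      r <- cpp_conv2d_backward(l$x, l$w, g, l$stride, l$pad, need_gx, TRUE)
      l$gw <- if (is.null(l$gw)) r$gw else l$gw + r$gw
      l$gb <- if (is.null(l$gb)) r$gb else l$gb + r$gb
      if (need_gx) r$gx else NULL
    },
    tconv = {
      # adjoint view: input grad is a plain convolution of the output grad
      r <- cpp_conv2d_backward(g, l$w, l$x, l$stride, l$pad, FALSE, TRUE)
      l$gw <- if (is.null(l$gw)) r$gw else l$gw + r$gw
      dg <- dim(g)
      gbk <- colSums(matrix(g, dg[1] * dg[2]))
      gb <- rowSums(matrix(gbk, ncol = dg[4]))
      l$gb <- if (is.null(l$gb)) gb else l$gb + gb
      if (need_gx) cpp_conv2d_forward(g, l$w, numeric(dim(l$w)[4]),
                                      l$stride, l$pad) else NULL
    },
    instnorm = {
      d <- l$dims
      hw <- d[1] * d[2]
      gm <- matrix(g, hw)
      gcol <- l$gamma[l$colc]
      l$ggamma_acc <- (l$ggamma_acc %||% numeric(l$ch))
      l$gbeta_acc <- (l$gbeta_acc %||% numeric(l$ch))
      gg <- colSums(gm * l$xh)
      gb <- colSums(gm)
      for (c in seq_len(l$ch)) {
        sel <- l$colc == c
        l$ggamma_acc[c] <- l$ggamma_acc[c] + sum(gg[sel])
        l$gbeta_acc[c] <- l$gbeta_acc[c] + sum(gb[sel])
      }
      if (!need_gx) return(NULL)
      mg <- colMeans(gm)
      mgx <- colMeans(gm * l$xh)
      dx <- sweep(gm, 2, mg) - sweep(l$xh, 2, mgx, `*`)
      dx <- sweep(dx, 2, gcol * l$istd, `*`)
      array(dx, dim = d)
    },
    lrelu = {
      if (!need_gx) return(NULL)
      g * (l$pos + l$slope * !l$pos)
    },
    tanh = {
      if (!need_gx) return(NULL)
      g * (1 - l$y^2)
    },
    resblock = {
      gh <- g
      for (s in rev(l$sub)) gh <- layer_backward(s, gh, TRUE)
      g + gh
    },
    stop_synthmv("unknown layer type %s", l$type))
}

net_forward <- function(net, x) {
  for (l in net) x <- layer_forward(l, x)
  x
}

net_backward <- function(net, g, need_input_grad = FALSE) {
  n <- length(net)
  for (i in rev(seq_len(n))) {
    need <- need_input_grad || i > 1L
    g <- layer_backward(net[[i]], g, need)
  }
  g
}

# flatten resblocks so optimizers see every parametrized layer
flat_layers <- function(net) {
  out <- list()
  for (l in net) {
    if (l$type == "resblock") out <- c(out, l$sub) else out <- c(out, list(l))
  }
  Filter(function(l) l$type %in% c("conv", "tconv", "instnorm"), out)
}

param_names <- function(l) {
  if (l$type == "instnorm") c("gamma", "beta") else c("w", "b")
}

grad_name <- function(l, p) {
  if (l$type == "instnorm") paste0("g", p, "_acc") else paste0("g", p)
}

zero_grads <- function(net) {
  for (l in flat_layers(net)) {
    for (p in param_names(l)) {
      gn <- grad_name(l, p)
      assign(gn, NULL, envir = l)
    }
  }
  invisible(NULL)
}

param_count <- function(net) {
  sum(vapply(flat_layers(net), function(l)
    sum(vapply(param_names(l), function(p) length(get(p, envir = l)),
               numeric(1))), numeric(1)))
}

adam_init <- function(net) {
  for (l in flat_layers(net)) {
    for (p in param_names(l)) {
      assign(paste0("adam_m_", p), 0 * get(p, envir = l), envir = l)
      assign(paste0("adam_v_", p), 0 * get(p, envir = l), envir = l)
    }
  }
  invisible(NULL)
}

adam_step <- function(net, lr, t, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in flat_layers(net)) {
    for (p in param_names(l)) {
      g <- get0(grad_name(l, p), envir = l)
      if (is.null(g)) next
      m <- beta1 * get(paste0("adam_m_", p), envir = l) + (1 - beta1) * g
      v <- beta2 * get(paste0("adam_v_", p), envir = l) + (1 - beta2) * g^2
      assign(paste0("adam_m_", p), m, envir = l)
      assign(paste0("adam_v_", p), v, envir = l)
      upd <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
      assign(p, get(p, envir = l) - upd, envir = l)
    }
  }
  invisible(NULL)
}

# weight snapshot / restore, for serializable checkpoints with bit-identical
# forward outputs after reload
net_snapshot <- function(net) {
  lapply(flat_layers(net), function(l)
    setNames(lapply(param_names(l), get, envir = l), param_names(l)))
}

net_restore <- function(net, snap) {
  fl <- flat_layers(net)
  stopifnot(length(fl) == length(snap))
  for (i in seq_along(fl)) {
    for (p in names(snap[[i]])) assign(p, snap[[i]][[p]], envir = fl[[i]])
  }
  invisible(net)
}

#' Generator configuration
#'
#' ResNet-style translation generator: a three-convolution encoder (stem
#' plus two stride-2 downsamplings), `n_residual_blocks` residual blocks,
#' and a three-transposed-convolution decoder, with instance normalization
#' and leaky-ReLU after internal layers and a bounded (tanh) output matching
#' the [-1, 1] input normalization. Output spatial dims equal input dims for
#' inputs divisible by `2^(n_down - 1)`.
#'
#' @param in_channels input channels (1 for single-modality slices).
#' @param base_channels stem width (64 at full scale; use 8-16 for small
#'   CPU experiments).
#' @param n_residual_blocks number of residual blocks (default 9).
#' @param n_down encoder depth (3 convolutions; the two after the stem
#'   downsample).
#' @param slope leaky-ReLU negative slope.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(in_channels = 1L, base_channels = 64L,
                             n_residual_blocks = 9L, n_down = 3L,
                             slope = 0.2) {
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 n_down = as.integer(n_down), slope = slope,
                 norm = "instance", activation = "lrelu"),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Patch-level discriminator: five convolutional layers (kernel 4), each
#' followed by leaky-ReLU except the final linear layer, producing a spatial
#' map of sub-regional authenticity scores rather than a scalar.
#'
#' @param in_channels input channels.
#' @param base_channels first-layer width.
#' @param n_layers convolution count (5).
#' @param strides per-layer strides (default `c(2, 2, 2, 1, 1)`).
#' @param slope leaky-ReLU negative slope.
#' @return list of class `discriminator_config`.
#' @export
discriminator_config <- function(in_channels = 1L, base_channels = 64L,
                                 n_layers = 5L, strides = c(2, 2, 2, 1, 1),
                                 slope = 0.2) {
  if (length(strides) != n_layers)
    stop_synthmv("strides must have length n_layers")
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_layers = as.integer(n_layers),
                 strides = as.integer(strides), slope = slope),
            class = "discriminator_config")
}

#' Build a generator network
#'
#' @param cfg a [generator_config()]. Weight initialization draws from the
#'   session RNG; seed before calling for reproducibility.
#' @return list of layers (class `synthmv_net`), usable with
#'   [translate()] and the training functions.
#' @export
build_generator <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  c0 <- cfg$base_channels
  sl <- cfg$slope
  net <- list(
    layer_conv(cfg$in_channels, c0, 7, 1, 3),
    layer_instnorm(c0), layer_lrelu(sl),
    layer_conv(c0, 2 * c0, 3, 2, 1),
    layer_instnorm(2 * c0), layer_lrelu(sl),
    layer_conv(2 * c0, 4 * c0, 3, 2, 1),
    layer_instnorm(4 * c0), layer_lrelu(sl))
  for (i in seq_len(cfg$n_residual_blocks))
    net <- c(net, list(layer_resblock(4 * c0, sl)))
  net <- c(net, list(
    layer_tconv(4 * c0, 2 * c0, 3, 2, 1, 1),
    layer_instnorm(2 * c0), layer_lrelu(sl),
    layer_tconv(2 * c0, c0, 3, 2, 1, 1),
    layer_instnorm(c0), layer_lrelu(sl),
    layer_tconv(c0, 1L, 7, 1, 3, 0),
    layer_tanh()))
  structure(net, class = "synthmv_net", role = "generator",
            divisor = 2^(cfg$n_down - 1L))
}

#' Build a discriminator network
#'
#' @param cfg a [discriminator_config()].
#' @return list of layers (class `synthmv_net`).
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  stopifnot(inherits(cfg, "discriminator_config"))
  c0 <- cfg$base_channels
  ch <- c(cfg$in_channels, c0, 2 * c0, 4 * c0, 8 * c0, 1L)
  net <- list()
  for (i in seq_len(cfg$n_layers)) {
    net <- c(net, list(layer_conv(ch[i], ch[i + 1], 4, cfg$strides[i], 1)))
    if (i > 1 && i < cfg$n_layers) net <- c(net, list(layer_instnorm(ch[i + 1])))
    if (i < cfg$n_layers) net <- c(net, list(layer_lrelu(cfg$slope)))
  }
  structure(net, class = "synthmv_net", role = "discriminator")
}

# generator forward with the divisibility contract from the config
generator_forward <- function(net, x) {
  dv <- attr(net, "divisor") %||% 4L
  d <- dim(x)
  if (d[1] %% dv != 0 || d[2] %% dv != 0)
    stop_synthmv("input %d x %d not supported: spatial dims must be divisible by %d",
                 d[1], d[2], dv)
  net_forward(net, x)
}
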