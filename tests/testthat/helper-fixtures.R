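# shared fixtures, built once per test run

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

fixture_render <- function() cached("render", {
  lib <- default_phantom_library()
  dev <- default_device_library()
  spec <- lib$p1
  spec$device <- dev$d01
  list(spec = spec, r = render_attenuation_map(spec))
})

fixture_design <- function(n = 6, seed = 5, ...) {
  study_design(combinations = default_combinations()[seq_len(n), ],
               seed = seed, ...)
}

fixture_cases <- function() cached("cases6", generate_study(fixture_design()))

# smooth random field representable by a downsampling generator
smooth_field <- function(n = 32) {
  g <- expand.grid(x = seq(0, 1, length.out = n), y = seq(0, 1, length.out = n))
  z <- 0
  for (k in 1:4)
    z <- z + rnorm(1, 0, 0.4) *
      sin(2 * pi * (runif(1, 0.5, 2) * g$x + runif(1, 0.5, 2) * g$y + runif(1)))
  matrix(tanh(z), n, n)
}

# random compact mask (ellipsoid blob) inside a small grid
rand_mask <- function(dims = c(12, 12, 3)) {
  repeat {
    ctr <- runif(3, 0.25, 0.75) * dims
    rad <- runif(3, 1.2, 0.45 * dims)
    idx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                       k = seq_len(dims[3]))
    m <- array(((idx$i - ctr[1]) / rad[1])^2 + ((idx$j - ctr[2]) / rad[2])^2 +
                 ((idx$k - ctr[3]) / rad[3])^2 <= 1, dim = dims)
    if (any(m)) return(m)
  }
}

# independent brute-force surface-distance oracle: explicit loops only
brute_surface_pts <- function(m, spacing) {
  d <- dim(m)
  offs <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  pts <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    on_surface <- FALSE
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3] ||
          !m[ii, jj, kk]) { on_surface <- TRUE; break }
    }
    if (on_surface) pts[[length(pts) + 1L]] <- c(i, j, k) * spacing
  }
  do.call(rbind, pts)
}

brute_directed <- function(pa, pb) {
  vapply(seq_len(nrow(pa)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(pb))) {
      dd <- sqrt(sum((pa[i, ] - pb[j, ])^2))
      if (dd < best) best <- dd
    }
    best
  }, numeric(1))
}

brute_metrics <- function(A, B, spacing = c(1, 1, 1), tol = 1) {
  pa <- brute_surface_pts(A, spacing)
  pb <- brute_surface_pts(B, spacing)
  d_ab <- brute_directed(pa, pb)
  d_ba <- brute_directed(pb, pa)
  pooled <- sort(c(d_ab, d_ba))
  n <- length(pooled)
  h <- (n - 1) * 0.95 + 1
  lo <- floor(h)
  q95 <- pooled[lo] + (h - lo) * (pooled[min(lo + 1, n)] - pooled[lo])
  list(dsc = 2 * sum(A & B) / (sum(A) + sum(B)),
       sdsc = (sum(d_ab <= tol) + sum(d_ba <= tol)) / (length(d_ab) + length(d_ba)),
       hd95 = q95,
       msd = mean(d_ab))
}
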