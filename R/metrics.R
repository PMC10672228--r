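#' Automatic device contouring by thresholding
#'
#' Stand-in for manual expert delineation: threshold, per-slice largest
#' connected component, hole fill. The default threshold is the midpoint
#' between soft tissue and device intensity on the MV scale.
#'
#' @param image an [image_volume()] in HU.
#' @param threshold HU; default 200 (midpoint of MV soft tissue ~0 HU and
#'   device 400 HU).
#' @return Object of class `contour_mask`: `mask` (binary array), `spacing`.
#' @export
auto_contour_device <- function(image, threshold = 200) {
  stopifnot(is_image_volume(image))
  raw <- image$data > threshold
  if (!any(raw))
    stop_synthmv("no voxels above %g HU: contouring failed", threshold)
  d <- dim(raw)
  mask <- array(FALSE, dim = d)
  for (s in seq_len(d[3]))
    if (any(raw[, , s])) mask[, , s] <- largest_component_fill(raw[, , s])
  contour_mask(mask, image$spacing)
}

#' Binary contour mask with physical spacing
#' @param mask binary array (2D or 3D).
#' @param spacing mm per axis.
#' @return Object of class `contour_mask`.
#' @export
contour_mask <- function(mask, spacing = c(1, 1, 1)) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop_synthmv("spacing must be strictly positive")
  structure(list(mask = mask != 0, spacing = as.numeric(spacing[1:3])),
            class = "contour_mask")
}

as_contour_mask <- function(x) {
  if (inherits(x, "contour_mask")) return(x)
  if (is_image_volume(x)) return(contour_mask(x$data > 0.5, x$spacing))
  contour_mask(x)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`: region overlap relative to the two
#' mask sizes, 1 for a perfect match.
#'
#' @param a,b congruent `contour_mask` (or binary array / mask volume)
#'   objects.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as_contour_mask(a); b <- as_contour_mask(b)
  if (!identical(dim(a$mask), dim(b$mask)))
    stop_synthmv("masks are not congruent")
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0) stop_synthmv("Dice is undefined for two empty masks")
  2 * sum(a$mask & b$mask) / (na + nb)
}

# surface voxels: foreground with at least one face-neighbour background
# (out-of-grid counts as background)
surface_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  sub <- function(i, j, k) pad[i, j, k, drop = FALSE]
  core <- sub(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1))
  nb <- sub(1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)) &
    sub(3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)) &
    sub(2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)) &
    sub(2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)) &
    sub(2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]) &
    sub(2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2))
  which(core & !nb, arr.ind = TRUE)
}

#' Directed surface-distance multisets between two masks
#'
#' Surface voxels are foreground voxels with a face-neighbour background
#' voxel; distances are exact nearest-surface-point Euclidean distances in
#' physical millimetres (anisotropic spacing honoured).
#'
#' @param a,b `contour_mask` objects (or coercibles), congruent grids.
#' @return list with `d_ab` (distances from each surface point of `a` to
#'   the surface of `b`) and `d_ba`, both in mm.
#' @export
surface_distances <- function(a, b) {
  a <- as_contour_mask(a); b <- as_contour_mask(b)
  if (!identical(dim(a$mask), dim(b$mask)))
    stop_synthmv("masks are not congruent")
  if (!any(a$mask) || !any(b$mask))
    stop_synthmv("surface distances require two non-empty masks")
  sa <- surface_voxels(a$mask)
  sb <- surface_voxels(b$mask)
  pa <- sweep(sa, 2, a$spacing, `*`)
  pb <- sweep(sb, 2, b$spacing, `*`)
  # exact all-pairs nearest distances (surfaces are small point sets);
  # per-axis differencing keeps squared distances exact, so points lying
  # precisely at a tolerance radius classify correctly
  d2 <- outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2 +
    outer(pa[, 3], pb[, 3], `-`)^2
  list(d_ab = unname(sqrt(apply(d2, 1, min))),
       d_ba = unname(sqrt(apply(d2, 2, min))))
}

#' Surface Dice at a tolerance
#'
#' Fraction of the two masks' combined surface points whose nearest
#' opposite-surface distance is within `tol` millimetres (1 mm by default).
#'
#' @inheritParams surface_distances
#' @param tol agreement tolerance, mm.
#' @return scalar in [0, 1].
#' @export
surface_dice <- function(a, b, tol = 1) {
  d <- surface_distances(a, b)
  (sum(d$d_ab <= tol) + sum(d$d_ba <= tol)) /
    (length(d$d_ab) + length(d$d_ba))
}

#' 95th-percentile Hausdorff distance
#'
#' 95th percentile (linear interpolation between order statistics) of the
#' pooled symmetric surface-distance multiset, robust to boundary outliers.
#'
#' @inheritParams surface_distances
#' @param probs percentile (default 0.95).
#' @return distance, mm.
#' @export
hd95 <- function(a, b, probs = 0.95) {
  d <- surface_distances(a, b)
  unname(quantile(c(d$d_ab, d$d_ba), probs = probs, type = 7))
}

#' Mean surface distance
#'
#' Mean of the directed distances from the reference contour `a` to the
#' evaluated contour `b`; set `symmetric = TRUE` to average both directions.
#'
#' @inheritParams surface_distances
#' @param symmetric pool both directed multisets before averaging.
#' @return distance, mm.
#' @export
msd <- function(a, b, symmetric = FALSE) {
  d <- surface_distances(a, b)
  if (symmetric) mean(c(d$d_ab, d$d_ba)) else mean(d$d_ab)
}

#' Two-tailed Wilcoxon rank-sum test
#'
#' Midranks for ties. When `n + m <= 12` the two-tailed p-value is computed
#' exactly by full enumeration of all rank assignments (a permutation null,
#' valid with ties); otherwise a normal approximation with tie and
#' continuity corrections is used. The method applied is reported.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop_synthmv("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))                      # midranks
  w <- sum(r[seq_len(n)])
  if (n + m <= 12) {
    combs <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[combs], nrow = n))
    p <- min(1, 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9)))
    method <- "exact enumeration"
  } else {
    mu <- n * (m + n + 1) / 2
    ties <- table(r)
    sig2 <- n * m / 12 * ((n + m + 1) -
                            sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = w, p_value = p, method = method)
}

#' All four contour metrics for one mask pair
#'
#' @param reference,evaluated `contour_mask` objects: the contour on the
#'   real MV image and the contour on the synthetic MV image.
#' @param tol surface-Dice tolerance, mm.
#' @return one-row tibble with `dsc`, `sdsc_1mm`, `hd95_mm`, `msd_mm`.
#' @export
contour_metrics <- function(reference, evaluated, tol = 1) {
  reference <- as_contour_mask(reference)
  evaluated <- as_contour_mask(evaluated)
  d <- surface_distances(reference, evaluated)
  pooled <- c(d$d_ab, d$d_ba)
  tibble::tibble(
    dsc = dice(reference, evaluated),
    sdsc_1mm = (sum(d$d_ab <= tol) + sum(d$d_ba <= tol)) /
      (length(d$d_ab) + length(d$d_ba)),
    hd95_mm = unname(quantile(pooled, 0.95, type = 7)),
    msd_mm = mean(d$d_ab))
}
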