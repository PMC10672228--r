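#' Parallel-beam sinogram of a 2D slice
#'
#' Line sums over `n_angles` projections evenly spaced on half a turn.
#' Intensities are shifted so air (-1000 HU) projects to zero, which keeps
#' the multiplicative streak corruption physically sensible.
#'
#' @param slice numeric matrix (HU).
#' @param n_angles number of projection angles over 180 degrees.
#' @return list with `sino` (detector x angle matrix) and `angles` (radians).
#' @export
radon_sinogram <- function(slice, n_angles = 180L) {
  angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  list(sino = cpp_radon(slice + 1000, angles), angles = angles)
}

#' Filtered back-projection reconstruction
#'
#' Ramp-filtered (frequency domain, zero-padded) back-projection; the inverse
#' of [radon_sinogram()] up to discretization error. Output is shifted back
#' onto the HU scale.
#'
#' @param sino detector x angle sinogram from [radon_sinogram()].
#' @param angles projection angles, radians.
#' @param n output grid size (pixels per axis).
#' @return numeric n x n matrix, HU.
#' @export
fbp_reconstruct <- function(sino, angles, n) {
  nd <- nrow(sino)
  m <- 2^ceiling(log2(2 * nd))
  pad <- rbind(sino, matrix(0, m - nd, ncol(sino)))
  # band-limited discrete ramp (Kak & Slaney): avoids the DC bias of a
  # plain |f| filter
  nvec <- c(seq(0, m / 2), seq(-m / 2 + 1, -1))
  f <- numeric(m)
  f[1] <- 0.25
  odd <- which(nvec %% 2 != 0)
  f[odd] <- -1 / (pi * nvec[odd])^2
  filt <- 2 * Re(stats::fft(f))
  Fs <- stats::mvfft(pad)
  fs <- Re(stats::mvfft(Fs * filt, inverse = TRUE)) / m
  cpp_backproject(fs[seq_len(nd), , drop = FALSE], angles, n, n) - 1000
}

#' Simulate a kV acquisition with metal streak artifacts
#'
#' Forward-projects each slice to a parallel-beam sinogram, corrupts every
#' ray whose path intersects the device (multiplicative under/over
#' attenuation with sign alternating across neighbouring rays, scaled by the
#' device path length), reconstructs by filtered back-projection, adds
#' zero-mean Gaussian noise on the reconstructed HU scale, and clips to
#' [-1000, 2000] HU. With `streak_strength = 0` and `noise_sd = 0` this
#' reduces to a plain FBP rendering of the attenuation map.
#'
#' @param mu_map [image_volume()] attenuation map (HU).
#' @param device_mask binary array congruent with `mu_map` (or `NULL`).
#' @param noise_sd image-domain noise standard deviation, HU.
#' @param streak_strength non-negative multiplicative corruption amplitude.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param n_angles projections per half-turn.
#' @param modality label for the output volume.
#' @return [image_volume()] of the reconstructed, clipped slices.
#' @export
simulate_kv_slice <- function(mu_map, device_mask = NULL, noise_sd = 0,
                              streak_strength = 0, seed = 1L,
                              n_angles = 180L, modality = "kv_cbct") {
  stopifnot(is_image_volume(mu_map))
  if (streak_strength < 0) stop_synthmv("streak_strength must be >= 0")
  d <- dim(mu_map$data)
  if (!is.null(device_mask) && !identical(dim(device_mask), d))
    stop_synthmv("mu_map and device_mask are not congruent")
  out <- array(0, dim = d)
  with_seed(seed, {
    recon_cache <- NULL
    prev_slice <- NULL
    for (s in seq_len(d[3])) {
      sl <- mu_map$data[, , s]
      dv <- if (is.null(device_mask)) NULL else device_mask[, , s]
      if (is.null(prev_slice) || !identical(sl, prev_slice)) {
        rs <- radon_sinogram(sl, n_angles)
        sino <- rs$sino
        if (!is.null(dv) && any(dv > 0)) {
          dsino <- cpp_radon(dv * 1, rs$angles)
          w <- dsino / max(dsino)
          # alternating over/under-attenuation in two-detector-bin bands,
          # flipped between neighbouring angles, plus a net under-attenuation
          # component (beam hardening depresses measured line integrals
          # through metal; scatter raises them on other rays)
          alt <- outer(seq_len(nrow(sino)), seq_len(ncol(sino)),
                       function(t, a) (-1)^(t %/% 2 + a))
          sino <- sino * (1 + streak_strength * w * (alt - 0.3))
        }
        recon_cache <- fbp_reconstruct(sino, rs$angles, d[1])
        prev_slice <- sl
      }
      noisy <- recon_cache
      if (noise_sd > 0) noisy <- noisy + rnorm(length(noisy), 0, noise_sd)
      if (any(!is.finite(noisy))) stop_synthmv("non-finite reconstruction")
      out[, , s] <- pmin(pmax(noisy, -1000), 2000)
    }
  })
  image_volume(out, spacing = mu_map$spacing, origin = mu_map$origin,
               modality = modality)
}

# Monotone piecewise-linear compression of the kV HU range onto the MV
# range [-1000, 400]; control points keep air/lung/soft/bone/device
# separable with the device mapping to the range maximum.
mv_map_points <- function() {
  list(x = c(-1000, -500, 0, 100, 1000, 2000),
       y = c(-1000, -400, -20, 30, 180, 400))
}

#' Monotone kV-to-MV intensity mapping
#'
#' @param x HU values on the kV scale (clipped into [-1000, 2000]).
#' @return HU values on the MV scale [-1000, 400].
#' @export
mv_intensity_map <- function(x) {
  p <- mv_map_points()
  approx(p$x, p$y, xout = pmin(pmax(x, -1000), 2000), rule = 2)$y
}

#' Simulate an MV acquisition
#'
#' Streak-free rendering: the attenuation map is compressed into the MV
#' intensity range [-1000, 400] HU by a monotone piecewise-linear map, then
#' additive Gaussian noise is applied (MV noise exceeds kV noise by default,
#' reflecting the poorer low-contrast quality of MV imaging). The device
#' remains the maximum-intensity structure.
#'
#' @inheritParams simulate_kv_slice
#' @return [image_volume()] clipped to [-1000, 400] HU.
#' @export
simulate_mv_slice <- function(mu_map, noise_sd = 0, seed = 1L,
                              modality = "mv_cbct") {
  stopifnot(is_image_volume(mu_map))
  d <- dim(mu_map$data)
  base <- array(mv_intensity_map(mu_map$data), dim = d)
  out <- with_seed(seed, {
    x <- base
    if (noise_sd > 0) x <- x + array(rnorm(length(x), 0, noise_sd), dim = d)
    pmin(pmax(x, -1000), 400)
  })
  image_volume(out, spacing = mu_map$spacing, origin = mu_map$origin,
               modality = modality)
}

#' Study design: which combinations to image, and how
#'
#' Defaults emulate the study design of the source experiment: 10 devices x
#' 4 phantoms with 5 pairs deterministically omitted (the last 5 in
#' lexicographic order) giving 35 combinations, each imaged in three
#' modalities (kV CT, kV CBCT, MV CBCT); CT misaligned versus the CBCT pair
#' by a random in-plane rigid offset (sd 3 mm translation per axis, 2 deg
#' rotation); per-modality noise; kV streak strengths reflecting iterative
#' metal-artifact-reduced CT (weaker) versus CBCT (stronger).
#'
#' @param combinations tibble/data.frame with `device_id`, `phantom_id`.
#' @param modalities modality labels per combination.
#' @param misalignment_sd list with `translation_mm`, `rotation_deg`.
#' @param noise_levels named per-modality HU noise sd.
#' @param streak_strength named kV streak amplitudes.
#' @param n_angles projections per half-turn.
#' @param seed integer.
#' @return Object of class `study_design`.
#' @export
study_design <- function(combinations = default_combinations(),
                         modalities = c("ct", "kv_cbct", "mv_cbct"),
                         misalignment_sd = list(translation_mm = 3, rotation_deg = 2),
                         noise_levels = c(ct = 15, kv_cbct = 30, mv_cbct = 40),
                         streak_strength = c(ct = 0.6, kv_cbct = 1.2),
                         n_angles = 180L,
                         seed = 1L) {
  combinations <- tibble::as_tibble(combinations)
  stopifnot(all(c("device_id", "phantom_id") %in% names(combinations)))
  if (anyDuplicated(combinations[c("device_id", "phantom_id")]))
    stop_synthmv("combinations must be unique")
  if (length(modalities) == 0) stop_synthmv("modalities must be non-empty")
  structure(list(combinations = combinations, modalities = modalities,
                 misalignment_sd = misalignment_sd,
                 noise_levels = noise_levels,
                 streak_strength = streak_strength,
                 n_angles = as.integer(n_angles),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Default 35-combination design
#'
#' All 40 device x phantom pairs in lexicographic order with the last 5
#' dropped, matching the study's count of 35 imaged combinations.
#' @return tibble with `device_id`, `phantom_id`.
#' @export
default_combinations <- function() {
  all <- tidyr::expand_grid(device_id = sprintf("d%02d", 1:10),
                            phantom_id = paste0("p", 1:4))
  all <- dplyr::arrange(all, .data$device_id, .data$phantom_id)
  all[seq_len(35), ]
}

#' Generate a full synthetic study
#'
#' One simulated case per combination: the kV CBCT and MV CBCT share one
#' frame (acquired "without moving the phantom"), the CT is rendered from
#' the same phantom but carries a random rigid in-plane misalignment whose
#' ground truth (the aligning transform that registration should recover) is
#' recorded. Fully reproducible from `design$seed`.
#'
#' @param design a [study_design()].
#' @param phantom_library named list of [phantom_spec()] (device slot free),
#'   containing every `phantom_id` in the design.
#' @param device_library named list of [device_spec()] containing every
#'   `device_id`.
#' @return list of `simulated_case` objects (`ct`, `kv_cbct`, `mv_cbct`,
#'   `device_mask`, `applied_misalignment`, `case_id`).
#' @export
generate_study <- function(design,
                           phantom_library = default_phantom_library(),
                           device_library = default_device_library()) {
  stopifnot(inherits(design, "study_design"))
  cmb <- design$combinations
  missing_p <- setdiff(unique(cmb$phantom_id), names(phantom_library))
  if (length(missing_p)) stop_synthmv("phantom spec missing for id: %s",
                                      paste(missing_p, collapse = ", "))
  missing_d <- setdiff(unique(cmb$device_id), names(device_library))
  if (length(missing_d)) stop_synthmv("device spec missing for id: %s",
                                      paste(missing_d, collapse = ", "))
  lapply(seq_len(nrow(cmb)), function(i) {
    pid <- cmb$phantom_id[i]; did <- cmb$device_id[i]
    spec <- phantom_library[[pid]]
    spec$device <- device_library[[did]]
    rend <- render_attenuation_map(spec)
    s0 <- derive_seed(design$seed, i)
    kv <- simulate_kv_slice(rend$image, rend$device_mask,
                            noise_sd = design$noise_levels[["kv_cbct"]],
                            streak_strength = design$streak_strength[["kv_cbct"]],
                            seed = derive_seed(s0, 1), n_angles = design$n_angles,
                            modality = "kv_cbct")
    mv <- simulate_mv_slice(rend$image,
                            noise_sd = design$noise_levels[["mv_cbct"]],
                            seed = derive_seed(s0, 2), modality = "mv_cbct")
    ct0 <- simulate_kv_slice(rend$image, rend$device_mask,
                             noise_sd = design$noise_levels[["ct"]],
                             streak_strength = design$streak_strength[["ct"]],
                             seed = derive_seed(s0, 3), n_angles = design$n_angles,
                             modality = "ct")
    mis <- with_seed(derive_seed(s0, 4), {
      sdt <- design$misalignment_sd$translation_mm
      sdr <- design$misalignment_sd$rotation_deg
      rigid_transform(
        angle_deg = if (sdr > 0) rnorm(1, 0, sdr) else 0,
        translation = if (sdt > 0) rnorm(2, 0, sdt) else c(0, 0),
        center = volume_center(kv))
    })
    # the CT is displaced by the *inverse* of the aligning transform, so
    # that registering CT onto the kV CBCT should recover `mis` itself
    ct <- if (abs(mis$angle_deg) + sum(abs(mis$translation)) > 0) {
      resample(ct0, invert_transform(mis), fill_value = -1000)
    } else ct0
    structure(list(
      case_id = paste0(did, "_", pid),
      device_id = did, phantom_id = pid,
      ct = ct, kv_cbct = kv, mv_cbct = mv,
      device_mask = image_volume(rend$device_mask * 1, spacing = kv$spacing,
                                 modality = "mask"),
      body_mask = rend$body_mask,
      mu_map = rend$image,
      applied_misalignment = mis
    ), class = "simulated_case")
  })
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("<simulated_case> %s: ct/kv_cbct/mv_cbct %s, device %d voxels\n",
              x$case_id, paste(dim(x$kv_cbct$data), collapse = "x"),
              sum(x$device_mask$data > 0)))
  invisible(x)
}

#' Random train/test partition of cases
#'
#' @param cases list of cases.
#' @param train_fraction fraction assigned to training (0 < f < 1);
#'   `round(f * n)` cases are selected.
#' @param seed integer driving the shuffle.
#' @return list with `train` and `test` lists (disjoint, exhaustive).
#' @export
split_dataset <- function(cases, train_fraction = 0.8, seed = 1L) {
  n <- length(cases)
  if (n < 2) stop_synthmv("need at least 2 cases to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_synthmv("train_fraction must be in (0, 1)")
  k <- round(train_fraction * n)
  idx <- with_seed(seed, sample.int(n))
  list(train = cases[sort(idx[seq_len(k)])],
       test = cases[sort(idx[-seq_len(k)])])
}

#' Export simulated cases as NIfTI volumes
#'
#' Writes `ct.nii.gz`, `kv_cbct.nii.gz`, `mv_cbct.nii.gz`,
#' `device_mask.nii.gz` per case plus a JSON sidecar with the ground-truth
#' misalignment.
#'
#' @param cases list of `simulated_case`.
#' @param dir output directory (one subdirectory per case).
#' @return `dir`, invisibly.
#' @export
export_cases <- function(cases, dir) {
  for (cs in cases) {
    d <- file.path(dir, cs$case_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    save_volume(cs$ct, file.path(d, "ct.nii.gz"))
    save_volume(cs$kv_cbct, file.path(d, "kv_cbct.nii.gz"))
    save_volume(cs$mv_cbct, file.path(d, "mv_cbct.nii.gz"))
    save_volume(cs$device_mask, file.path(d, "device_mask.nii.gz"))
    write_transform_json(cs$applied_misalignment,
                         file.path(d, "misalignment.json"))
  }
  invisible(dir)
}

#' Import a directory of cases
#'
#' Maps an on-disk layout (one directory per case holding `ct`, `kv_cbct`,
#' `mv_cbct` NIfTI volumes, file names matched case-insensitively by those
#' substrings) onto the same case structure the synthetic generator emits,
#' so downstream stages are source-agnostic. Cases with a missing modality
#' are skipped with a warning.
#'
#' @param root_dir directory of per-case subdirectories.
#' @return list of `simulated_case`-shaped objects (without ground truth
#'   unless a `misalignment.json` sidecar is present).
#' @export
import_real_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) stop_synthmv("no such directory: %s", root_dir)
  subs <- list.dirs(root_dir, recursive = FALSE)
  if (!length(subs)) {
    warning("no case directories found in ", root_dir)
    return(list())
  }
  find1 <- function(d, key) {
    f <- list.files(d, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    f[grepl(key, tolower(basename(f)), fixed = TRUE)][1]
  }
  out <- list()
  skipped <- 0L
  for (d in subs) {
    fs <- c(ct = find1(d, "ct"), kv = find1(d, "kv"), mv = find1(d, "mv"))
    # "ct" also matches kv_cbct/mv_cbct; prefer an exact-stem ct file
    cts <- list.files(d, pattern = "^ct\\.nii(\\.gz)?$", full.names = TRUE)
    if (length(cts)) fs["ct"] <- cts[1]
    if (anyNA(fs)) {
      warning("incomplete modality triplet in ", basename(d), "; case skipped")
      skipped <- skipped + 1L
      next
    }
    cs <- list(case_id = basename(d),
               ct = load_volume(fs[["ct"]], "ct"),
               kv_cbct = load_volume(fs[["kv"]], "kv_cbct"),
               mv_cbct = load_volume(fs[["mv"]], "mv_cbct"))
    mj <- file.path(d, "misalignment.json")
    if (file.exists(mj)) cs$applied_misalignment <- read_transform_json(mj)
    dm <- list.files(d, pattern = "^device_mask\\.nii(\\.gz)?$", full.names = TRUE)
    if (length(dm)) cs$device_mask <- load_volume(dm[1], "mask")
    out[[cs$case_id]] <- structure(cs, class = "simulated_case")
  }
  attr(out, "n_skipped") <- skipped
  out
}
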