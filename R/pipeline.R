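#' Experiment configuration
#'
#' One nested configuration drives the whole experiment (simulate, split,
#' register, preprocess, train, evaluate). Two profiles are built in:
#' `"full"` (256 x 256 grid at 1.5 mm, 35 combinations, 256-pixel patches,
#' full-width networks) and `"test"` (64 x 64 at 4 mm, 12 combinations,
#' 32-pixel patches, narrow networks) for CPU-scale runs. Every stage seed
#' is derived deterministically from the global seed.
#'
#' @param profile `"test"` or `"full"`.
#' @param seed global integer seed.
#' @param routes translation routes to train (`"ct2mv"`, `"kv2mv"`).
#' @param models model families to train (`"cgan"`, `"cyclegan"`).
#' @param out_dir optional output/cache directory.
#' @param ... named overrides of nested entries, e.g.
#'   `train = list(epochs = 2)`.
#' @return nested list of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("test", "full"), seed = 1L,
                              routes = c("ct2mv", "kv2mv"),
                              models = c("cgan", "cyclegan"),
                              out_dir = NULL, ...) {
  profile <- match.arg(profile)
  full <- profile == "full"
  cmb <- default_combinations()
  if (!full) cmb <- cmb[seq_len(12), ]
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    routes = routes,
    models = models,
    out_dir = out_dir,
    study = list(
      grid_shape = if (full) 256L else 64L,
      pixel_spacing = if (full) 1.5 else 4,
      slice_thickness = if (full) 2 else 4,
      n_slices = if (full) 8L else 3L,
      combinations = cmb,
      misalignment_sd = list(translation_mm = 3, rotation_deg = 2),
      noise_levels = c(ct = 15, kv_cbct = 30, mv_cbct = 40),
      streak_strength = c(ct = 0.6, kv_cbct = 1.2),
      n_angles = 180L
    ),
    split = list(train_fraction = 0.8),
    registration = list(shrink_factors = c(4L, 2L, 1L), bins = 50L,
                        max_iter = if (full) 200L else 100L),
    preprocess = list(kv_clip = kv_clip_range(), mv_clip = mv_clip_range(),
                      body_threshold = -400,
                      patch_size = if (full) 256L else 32L,
                      n_patches = if (full) 32L else 8L),
    model = list(base_channels = if (full) 64L else 8L,
                 n_residual_blocks = if (full) 9L else 1L,
                 disc_channels = if (full) 64L else 8L),
    train = list(epochs = if (full) 100L else 50L,
                 batch_size = if (full) 4L else 8L,
                 learning_rate = if (full) 2e-4 else 1e-3,
                 lambda_l1 = 100, lambda_cycle = 10,
                 beta1 = if (full) 0.5 else 0.9),
    evaluation = list(contour_threshold = mv_device_threshold(),
                      surface_tol_mm = 1)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' The configuration round-trips losslessly through its file form.
#' @param cfg an [experiment_config()].
#' @param path YAML file path.
#' @return `path` / the restored `experiment_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$study$combinations <- as.list(as.data.frame(x$study$combinations))
  # named numeric vectors serialize as YAML maps so names survive the trip
  x$study$noise_levels <- as.list(x$study$noise_levels)
  x$study$streak_strength <- as.list(x$study$streak_strength)
  x$preprocess$kv_clip <- as.list(x$preprocess$kv_clip)
  x$preprocess$mv_clip <- as.list(x$preprocess$mv_clip)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$study$combinations <- tibble::as_tibble(x$study$combinations)
  x$study$noise_levels <- unlist(x$study$noise_levels)
  x$study$streak_strength <- unlist(x$study$streak_strength)
  x$preprocess$kv_clip <- unlist(x$preprocess$kv_clip)
  x$preprocess$mv_clip <- unlist(x$preprocess$mv_clip)
  for (nm in c("grid_shape", "n_slices", "n_angles"))
    x$study[[nm]] <- as.integer(x$study[[nm]])
  structure(x, class = "experiment_config")
}

# cache a stage result under out_dir, keyed by a content hash
stage_cached <- function(out_dir, stage, key, compute) {
  if (is.null(out_dir)) return(compute())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(out_dir, sprintf("%s_%s.rds", stage, rlang::hash(key)))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

#' Register and align the CT of each case onto its CBCT frame
#'
#' @param cases list of simulated cases.
#' @param shrink_factors,bins,max_iter forwarded to [register_rigid()].
#' @return the cases, each with `ct_aligned` ([image_volume()]) and
#'   `registration` (the `registration_result`) attached.
#' @export
align_ct_cases <- function(cases, shrink_factors = c(4L, 2L, 1L), bins = 50L,
                           max_iter = 100L) {
  lapply(cases, function(cs) {
    reg <- register_rigid(cs$kv_cbct, cs$ct, shrink_factors = shrink_factors,
                          bins = bins, max_iter = max_iter)
    cs$registration <- reg
    cs$ct_aligned <- resample(cs$ct, reg$transform, reference = cs$kv_cbct)
    cs
  })
}

# clip + normalize one case's volumes and extract paired patches per route
case_patches <- function(cs, route, pp, seed) {
  input <- switch(route, ct2mv = cs$ct_aligned %||% cs$ct, kv2mv = cs$kv_cbct)
  kvc <- pp$kv_clip; mvc <- pp$mv_clip
  x <- normalize_for_network(clip_intensities(input, kvc[["lo"]], kvc[["hi"]]),
                             kvc[["lo"]], kvc[["hi"]])
  y <- normalize_for_network(clip_intensities(cs$mv_cbct, mvc[["lo"]], mvc[["hi"]]),
                             mvc[["lo"]], mvc[["hi"]])
  body <- compute_body_mask(cs$mv_cbct, pp$body_threshold)
  extract_patches(x, y, body, patch_size = pp$patch_size,
                  n_patches = pp$n_patches, seed = seed, case_id = cs$case_id)
}

#' Run the full experiment from one configuration
#'
#' Executes simulate, split, registration (CT routes only; the kV CBCT
#' shares the MV frame so its route skips registration), preprocessing,
#' training of every configured route x model, inference on the held-out
#' cases, and evaluation. Returns the comparison report plus a run manifest
#' (config snapshot, stage hashes, timestamps). With `out_dir` set, stage
#' results are cached by input hash so re-running evaluation does not
#' retrain.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print stage progress.
#' @return list with `report` (an `smv_report`), `translators`,
#'   `baseline` (raw-kV contour metrics), `cases`, `split`, `manifest`.
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  manifest <- list(config = unclass(cfg),
                   started = format(t0, "%Y-%m-%d %H:%M:%S"),
                   version = as.character(utils::packageVersion("synthmv")),
                   stages = list())
  st <- cfg$study
  design <- study_design(combinations = st$combinations,
                         misalignment_sd = st$misalignment_sd,
                         noise_levels = st$noise_levels,
                         streak_strength = st$streak_strength,
                         n_angles = st$n_angles,
                         seed = derive_seed(cfg$seed, 1))
  say("simulating %d combinations at %d px", nrow(st$combinations), st$grid_shape)
  plib <- default_phantom_library(grid_shape = st$grid_shape,
                                  pixel_spacing = st$pixel_spacing,
                                  slice_thickness = st$slice_thickness,
                                  n_slices = st$n_slices)
  cases <- stage_cached(cfg$out_dir, "simulate", list(design, st), function()
    generate_study(design, plib))
  manifest$stages$simulate <- list(n_cases = length(cases),
                                   hash = rlang::hash(lapply(cases, function(c) c$case_id)))

  split <- split_dataset(cases, cfg$split$train_fraction,
                         seed = derive_seed(cfg$seed, 2))
  manifest$stages$split <- list(n_train = length(split$train),
                                n_test = length(split$test))

  if ("ct2mv" %in% cfg$routes) {
    say("registering CT onto kV CBCT for %d cases",
        length(split$train) + length(split$test))
    rg <- cfg$registration
    split$train <- stage_cached(cfg$out_dir, "register_train",
                                list(design, rg), function()
      align_ct_cases(split$train, rg$shrink_factors, rg$bins, rg$max_iter))
    split$test <- stage_cached(cfg$out_dir, "register_test",
                               list(design, rg, "test"), function()
      align_ct_cases(split$test, rg$shrink_factors, rg$bins, rg$max_iter))
  }

  translators <- list()
  for (route in cfg$routes) {
    say("extracting patches for route %s", route)
    patches <- dplyr::bind_rows(lapply(seq_along(split$train), function(i)
      case_patches(split$train[[i]], route, cfg$preprocess,
                   seed = derive_seed(cfg$seed, 100 + i))))
    gen_cfg <- generator_config(base_channels = cfg$model$base_channels,
                                n_residual_blocks = cfg$model$n_residual_blocks)
    disc_cfg <- discriminator_config(base_channels = cfg$model$disc_channels)
    for (model in cfg$models) {
      say("training %s / %s on %d patches", model, route, nrow(patches))
      tcfg <- train_config(epochs = cfg$train$epochs,
                           batch_size = cfg$train$batch_size,
                           learning_rate = cfg$train$learning_rate,
                           lambda_l1 = cfg$train$lambda_l1,
                           lambda_cycle = cfg$train$lambda_cycle,
                           beta1 = cfg$train$beta1,
                           seed = derive_seed(cfg$seed, 200 + match(model, cfg$models) +
                                                10 * match(route, cfg$routes)))
      key <- list(design, route, model, cfg$model, cfg$train, cfg$preprocess)
      tr <- stage_cached(cfg$out_dir, paste0("train_", model, "_", route), key,
        function() {
          if (model == "cgan") {
            train_cgan(patches, gen_cfg, disc_cfg, tcfg, route = route,
                       norm_in = cfg$preprocess$kv_clip,
                       norm_out = cfg$preprocess$mv_clip)
          } else {
            train_cyclegan(patches$input, patches$target, gen_cfg, disc_cfg,
                           tcfg, route = route,
                           norm_in = cfg$preprocess$kv_clip,
                           norm_out = cfg$preprocess$mv_clip)$ab
          }
        })
      translators[[paste0(model, "_", route)]] <- tr
    }
  }
  manifest$stages$train <- list(routes = cfg$routes, models = cfg$models,
                                hash = rlang::hash(lapply(translators, function(t)
                                  t$trace[nrow(t$trace), ])))

  say("evaluating on %d held-out cases", length(split$test))
  report <- evaluate_models(split$test, translators,
                            contour_threshold = cfg$evaluation$contour_threshold,
                            tol = cfg$evaluation$surface_tol_mm)
  baseline <- kv_baseline_metrics(split$test,
                                  mv_threshold = cfg$evaluation$contour_threshold,
                                  tol = cfg$evaluation$surface_tol_mm)
  manifest$stages$evaluate <- list(hash = rlang::hash(report$per_case))
  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  list(report = report, translators = translators, baseline = baseline,
       cases = cases, split = split, manifest = manifest)
}
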