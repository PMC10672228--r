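#' Default device-contouring thresholds
#'
#' MV scale: midpoint of soft tissue (~0 HU) and device (400 HU). kV scale:
#' midpoint of soft tissue (~40 HU) and the clipped device intensity
#' (2000 HU).
#' @return threshold, HU.
#' @export
mv_device_threshold <- function() 200

#' @rdname mv_device_threshold
#' @export
kv_device_threshold <- function() 1020

#' Evaluate translators on a held-out test set
#'
#' For every case and every translator: translate the route's input volume,
#' auto-contour the device on the synthetic MV and on the reference MV
#' image, and compute all four contour-agreement metrics. Aggregates group
#' means and standard deviations per route/model and runs the two-tailed
#' rank-sum comparison of cGAN versus cycleGAN per metric per route.
#' Contouring failures are recorded as missing rows with a reason, never
#' silently dropped.
#'
#' @param test_cases list of cases (>= 2) as returned by [generate_study()]
#'   (with `ct_aligned` present for the CT route when registration ran).
#' @param translators named list of `trained_translator` objects, or bare
#'   functions `image -> image_volume` (used for oracle translators in
#'   tests); functions require names of the form `model_route`.
#' @param contour_threshold HU threshold for the MV-scale auto-contour.
#' @param tol surface-Dice tolerance, mm.
#' @return Object of class `smv_report` with `per_case`, `summary`, and
#'   `tests` tibbles.
#' @export
evaluate_models <- function(test_cases, translators,
                            contour_threshold = mv_device_threshold(),
                            tol = 1) {
  if (length(test_cases) < 2) stop_synthmv("need at least 2 test cases")
  rows <- list()
  for (cs in test_cases) {
    ref_mask <- tryCatch(auto_contour_device(cs$mv_cbct, contour_threshold),
                         error = function(e) e)
    for (nm in names(translators)) {
      tr <- translators[[nm]]
      if (inherits(tr, "trained_translator")) {
        model <- tr$model; route <- tr$route
      } else {
        parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
        model <- parts[1]; route <- paste(parts[-1], collapse = "_")
      }
      input <- switch(route,
                      ct2mv = cs$ct_aligned %||% cs$ct,
                      kv2mv = cs$kv_cbct,
                      cs$kv_cbct)
      res <- tryCatch({
        smv <- if (inherits(tr, "trained_translator")) translate(tr, input)
               else tr(input)
        if (inherits(ref_mask, "error")) stop(conditionMessage(ref_mask))
        smv_mask <- auto_contour_device(smv, contour_threshold)
        contour_metrics(ref_mask, smv_mask, tol = tol)
      }, error = function(e) {
        tibble::tibble(dsc = NA_real_, sdsc_1mm = NA_real_,
                       hd95_mm = NA_real_, msd_mm = NA_real_)
      })
      note <- if (anyNA(res$dsc)) "contouring or translation failed" else NA_character_
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(case_id = cs$case_id, route = route, model = model),
        res, tibble::tibble(note = note))
    }
  }
  per_case <- dplyr::bind_rows(rows)
  summary <- per_case |>
    tidyr::pivot_longer(dplyr::all_of(c("dsc", "sdsc_1mm", "hd95_mm", "msd_mm")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$route, .data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  tests <- compare_models_ranksum(per_case)
  structure(list(per_case = per_case, summary = summary, tests = tests),
            class = "smv_report")
}

# cGAN-vs-cycleGAN rank-sum comparison per metric per route
compare_models_ranksum <- function(per_case) {
  out <- list()
  for (rt in unique(per_case$route)) {
    sub <- dplyr::filter(per_case, .data$route == rt)
    models <- unique(sub$model)
    if (length(models) < 2) next
    prs <- utils::combn(models, 2, simplify = FALSE)
    for (pr in prs) {
      for (met in c("dsc", "sdsc_1mm", "hd95_mm", "msd_mm")) {
        x <- sub[[met]][sub$model == pr[1]]
        y <- sub[[met]][sub$model == pr[2]]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (!length(x) || !length(y)) next
        rs <- rank_sum_test(x, y)
        out[[length(out) + 1L]] <- tibble::tibble(
          route = rt, model_a = pr[1], model_b = pr[2], metric = met,
          statistic = rs$statistic, p_value = rs$p_value, method = rs$method)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.smv_report <- function(x, ...) {
  cat("<smv_report>\n")
  cat(sprintf("  %d per-case rows (%d cases x %d route/model combinations)\n",
              nrow(x$per_case), length(unique(x$per_case$case_id)),
              nrow(unique(x$per_case[c("route", "model")]))))
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"),
                             id_cols = c("route", "model"))
  print(as.data.frame(wide), digits = 3)
  if (nrow(x$tests)) {
    cat("  rank-sum model comparisons (two-tailed):\n")
    print(as.data.frame(x$tests[c("route", "metric", "model_a", "model_b",
                                  "p_value")]), digits = 3)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-case metric rows of a report
#' @param x an `smv_report`.
#' @param ... unused.
#' @return tibble of per-case metrics.
#' @export
tidy.smv_report <- function(x, ...) x$per_case

#' Group-level summary of a report
#' @param x an `smv_report`.
#' @param ... unused.
#' @return tibble of per-route/model means and standard deviations.
#' @export
glance.smv_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"),
                     id_cols = c("route", "model"))
}

#' Contour raw kV inputs as a no-translation baseline
#'
#' Thresholds the raw kV image at the kV-scale device threshold and scores
#' the resulting contour against the reference MV contour — the degradation
#' the translation models are meant to repair.
#'
#' @param test_cases list of cases.
#' @param kv_threshold HU threshold on the kV scale.
#' @param mv_threshold HU threshold for the reference MV contour.
#' @param tol surface-Dice tolerance, mm.
#' @return tibble of per-case metrics (`model` = "raw_kv").
#' @export
kv_baseline_metrics <- function(test_cases,
                                kv_threshold = kv_device_threshold(),
                                mv_threshold = mv_device_threshold(),
                                tol = 1) {
  rows <- lapply(test_cases, function(cs) {
    res <- tryCatch({
      ref <- auto_contour_device(cs$mv_cbct, mv_threshold)
      kvm <- auto_contour_device(cs$kv_cbct, kv_threshold)
      contour_metrics(ref, kvm, tol = tol)
    }, error = function(e)
      tibble::tibble(dsc = NA_real_, sdsc_1mm = NA_real_,
                     hd95_mm = NA_real_, msd_mm = NA_real_))
    dplyr::bind_cols(tibble::tibble(case_id = cs$case_id, route = "kv2mv",
                                    model = "raw_kv"), res)
  })
  dplyr::bind_rows(rows)
}
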