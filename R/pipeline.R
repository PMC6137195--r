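#' Configure an end-to-end adulteration analysis run
#'
#' Collects every setting of the simulate -> pretreat -> decompose ->
#' calibrate -> LOD pipeline in one serialisable list. The defaults
#' reproduce the study design: a 0-50 % v/v training series at a 1 %
#' gradient (51 samples), an external 0-50 % test series at a 5 % gradient
#' (11 samples), the 44 x 100 emission/time grids, Poisson noise at an
#' expected 1e4 peak counts, 4 PARAFAC factors, and a 5-hidden-unit ANN with
#' leave-one-out cross-validation.
#'
#' @param adulterant `"PO"` (peanut) or `"SO"` (sunflower) into camellia oil.
#' @param train_fractions,test_fractions adulteration levels (v/v).
#' @param peak_counts expected peak counts of the pure base oil.
#' @param noise `"poisson"` or `"none"`.
#' @param savgol,window,polyorder,snv_mode pretreatment settings
#'   (see [pretreat_cube()]).
#' @param n_factors PARAFAC factor number used for calibration.
#' @param scan_factors if `TRUE`, select the factor number by core
#'   consistency instead of using `n_factors` directly.
#' @param max_M,threshold factor-scan settings (see [select_factors()]).
#' @param parafac_tol,parafac_max_iter,parafac_starts ALS settings.
#' @param hidden_units,l2,ann_maxit,ann_starts ANN settings
#'   (see [tres_calibrate()]).
#' @param lod_levels adulteration levels for the LOD series (must include 0).
#' @param lod_replicates replicates per LOD level.
#' @param lod_summary `"total"` or `"late_window"` intensity summary.
#' @param alpha significance level of Duncan's test.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out_dir optional directory for persisted artifacts.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(adulterant = c("PO", "SO"),
                            train_fractions = adulteration_series(0, 0.50, 0.01),
                            test_fractions = adulteration_series(0, 0.50, 0.05),
                            peak_counts = 1e4,
                            noise = c("poisson", "none"),
                            savgol = TRUE, window = 5, polyorder = 2,
                            snv_mode = "off",
                            n_factors = 4, scan_factors = FALSE,
                            max_M = 6, threshold = 50,
                            parafac_tol = 1e-8, parafac_max_iter = 1500,
                            parafac_starts = 5,
                            hidden_units = 5, l2 = 5e-3, ann_maxit = 2000,
                            ann_starts = 3,
                            lod_levels = adulteration_series(0, 0.10, 0.01),
                            lod_replicates = 6,
                            lod_summary = c("total", "late_window"),
                            alpha = 0.05,
                            seed = 42L, out_dir = NULL) {
  structure(
    list(adulterant = match.arg(adulterant),
         train_fractions = train_fractions, test_fractions = test_fractions,
         peak_counts = peak_counts, noise = match.arg(noise),
         savgol = savgol, window = window, polyorder = polyorder,
         snv_mode = snv_mode,
         n_factors = n_factors, scan_factors = scan_factors,
         max_M = max_M, threshold = threshold,
         parafac_tol = parafac_tol, parafac_max_iter = parafac_max_iter,
         parafac_starts = parafac_starts,
         hidden_units = hidden_units, l2 = l2, ann_maxit = ann_maxit,
         ann_starts = ann_starts,
         lod_levels = lod_levels, lod_replicates = lod_replicates,
         lod_summary = match.arg(lod_summary), alpha = alpha,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full adulteration-analysis pipeline
#'
#' Executes, in order: TRES cube simulation for the training and external
#' test designs, spectral pretreatment, PARAFAC decomposition of the
#' training cube, ANN calibration of adulteration level from the sample
#' scores with leave-one-out cross-validation, projection and prediction of
#' the test samples, and the Duncan's-test detection limit on replicate
#' intensity series. Identical config + seed give identical numeric output;
#' when `out_dir` is set, the cubes and JSON reports are persisted there.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"tres_run"`: the PARAFAC model, calibration
#'   object, a `report` (all six calibration metrics, per-sample predictions,
#'   LOD) and a `manifest` (sample counts, seeds, stage timings).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  sys <- oil_system(config$adulterant)
  # noise = "none" is the ideal verification limit: no counting noise and no
  # sample-to-sample heterogeneity, so the cube is exactly trilinear in the
  # nominal mixing rule
  prep_cv <- 0.01
  if (config$noise == "none") {
    prep_cv <- 0
    strip <- function(p) {
      p$components <- lapply(p$components, function(cm) {
        cm$variability <- 0
        cm
      })
      p
    }
    sys <- lapply(sys, strip)
  }
  instrument <- instrument_model(peak_counts = config$peak_counts,
                                 noise = config$noise)

  train_cube <- clock("simulate_train", simulate_tres_cube(
    mixture_design(sys$base, sys$adulterant, config$train_fractions,
                   seed = config$seed, prep_cv = prep_cv), instrument))
  test_cube <- clock("simulate_test", simulate_tres_cube(
    mixture_design(sys$base, sys$adulterant, config$test_fractions,
                   seed = config$seed + 1L, prep_cv = prep_cv), instrument))

  train_pre <- clock("pretreat", pretreat_cube(
    train_cube, savgol = config$savgol, window = config$window,
    polyorder = config$polyorder, snv_mode = config$snv_mode))
  test_pre <- pretreat_cube(
    test_cube, savgol = config$savgol, window = config$window,
    polyorder = config$polyorder, snv_mode = config$snv_mode)

  scan <- NULL
  M <- config$n_factors
  if (isTRUE(config$scan_factors)) {
    scan <- clock("factor_scan", select_factors(
      train_pre, max_M = config$max_M, threshold = config$threshold,
      tol = config$parafac_tol, max_iter = config$parafac_max_iter,
      n_starts = config$parafac_starts, seed = config$seed))
    M <- scan$selected
  }
  model <- clock("parafac", parafac(
    train_pre, M, tol = config$parafac_tol,
    max_iter = config$parafac_max_iter, n_starts = config$parafac_starts,
    seed = config$seed))

  y_train <- 100 * config$train_fractions
  y_test <- 100 * config$test_fractions
  calib <- clock("calibrate", tres_calibrate(
    model$scores, y_train, hidden_units = config$hidden_units, l2 = config$l2,
    maxit = config$ann_maxit, n_starts = config$ann_starts,
    seed = config$seed))
  cv <- clock("cross_validate", cross_validate(
    model$scores, y_train, hidden_units = config$hidden_units, l2 = config$l2,
    maxit = config$ann_maxit, n_starts = config$ann_starts,
    seed = config$seed))
  test_scores <- project_scores(model, test_pre)
  ext <- clock("evaluate", evaluate_calibration(calib, test_scores, y_test))

  lod_groups <- clock("lod_simulate", simulate_intensity_groups(
    sys$base, sys$adulterant, instrument, config$lod_levels,
    n_replicates = config$lod_replicates, summary = config$lod_summary,
    seed = config$seed + 2L))
  lod <- determine_lod(lod_groups, alpha = config$alpha)

  report <- list(
    adulterant = config$adulterant,
    n_factors = M,
    explained_fraction = model$explained_fraction,
    rmsec = calib$rmsec, rmsecv = cv$rmsecv, rmsep = ext$rmsep,
    r2c = calib$r2c, r2cv = cv$r2cv, r2p = ext$r2p,
    lod_percent = lod$lod, lod_detected = lod$detected,
    predictions_train = as.numeric(calib$fitted),
    predictions_cv = as.numeric(cv$predictions_cv),
    predictions_test = as.numeric(ext$predictions),
    y_train = y_train, y_test = y_test
  )
  manifest <- list(
    package = "tresoil",
    version = as.character(utils::packageVersion("tresoil")),
    n_train = length(config$train_fractions),
    n_test = length(config$test_fractions),
    seed = config$seed,
    stage_seeds = list(train = config$seed, test = config$seed + 1L,
                       lod = config$seed + 2L),
    noise = config$noise,
    timings_s = as.list(timings)
  )

  run <- structure(
    list(config = config, train_cube = train_cube, test_cube = test_cube,
         model = model, factor_scan = scan, calibration = calib,
         cv = cv, external = ext, lod = lod, report = report,
         manifest = manifest),
    class = "tres_run"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cube(train_cube, file.path(config$out_dir, "train_cube.txt"))
    write_cube(test_cube, file.path(config$out_dir, "test_cube.txt"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.tres_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("TRES adulteration analysis (%s into CO), %d + %d samples\n",
              r$adulterant, x$manifest$n_train, x$manifest$n_test))
  cat(sprintf("  PARAFAC: %d factors, explained fraction %.5f\n",
              r$n_factors, r$explained_fraction))
  cat(sprintf("  RMSEC  %.3f %%   R2c  %.5f\n", r$rmsec, r$r2c))
  cat(sprintf("  RMSECV %.3f %%   R2cv %.5f\n", r$rmsecv, r$r2cv))
  cat(sprintf("  RMSEP  %.3f %%   R2p  %.5f\n", r$rmsep, r$r2p))
  if (r$lod_detected) {
    cat(sprintf("  LOD: %g%% (Duncan's test, alpha = %g)\n",
                r$lod_percent, x$config$alpha))
  } else {
    cat("  LOD: not detected within the tested levels\n")
  }
  invisible(x)
}
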