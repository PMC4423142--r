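#' Run the full QSAR modelling pipeline
#'
#' Orchestrates descriptor-matrix cleanup, calibration/validation
#' splitting, CDFS stepwise-MLR and GA-PLS model building,
#' Y-randomization and the leverage applicability domain, writing every
#' artifact (model JSONs, model report CSV, Y-randomization CSV, Williams
#' CSV, run manifest) under `output_dir`. Given the same configuration and
#' master seed the run is fully deterministic.
#'
#' The configuration is a named list (or a YAML file path with the same
#' keys): `x_csv`/`y_csv` for input CSVs (first column = compound id), or
#' `simulate_seed` to use the built-in synthetic bundle instead; optional
#' `r_cut`, `min_sd`, `min_unique_fraction`, `validation_fraction`,
#' `n_splits`, `keep_threshold`, `ga` (a list of [ga_config()] arguments),
#' `seed` (master seed, required), `output_dir` (required).
#'
#' @param config named list or path to a YAML file.
#' @return invisible list with the fitted `cdfs` and `gapls` objects and
#'   the manifest, its elements also persisted under `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$output_dir),
            !is.null(config$seed))
  seed <- as.integer(config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(...) file.path(config$output_dir, ...)

  if (!is.null(config$x_csv)) {
    for (f in c(config$x_csv, config$y_csv))
      if (!file.exists(f)) stop("input file not found: ", f)
    Xdf <- utils::read.csv(config$x_csv, check.names = FALSE)
    X <- as.matrix(Xdf[, -1L, drop = FALSE])
    rownames(X) <- Xdf[[1L]]
    ydf <- utils::read.csv(config$y_csv, check.names = FALSE)
    y <- ydf[[2L]][match(rownames(X), ydf[[1L]])]
    if (anyNA(y)) stop("activity missing for some compounds in y_csv")
  } else {
    bundle <- make_regression_dataset(
      seed = if (is.null(config$simulate_seed)) seed else
        as.integer(config$simulate_seed))
    X <- bundle$X; y <- bundle$y
  }

  cfgv <- function(key, default)
    if (is.null(config[[key]])) default else config[[key]]

  X1 <- drop_near_constant(X, cfgv("min_unique_fraction", 0.1),
                           cfgv("min_sd", 1e-8))
  X2 <- collinearity_filter(X1, y, cfgv("r_cut", 0.9))
  filter_log <- list(near_constant_removed = attr(X1, "removed"),
                     collinear_removed = attr(X2, "removed"),
                     p_in = ncol(X), p_out = ncol(X2))
  jsonlite::write_json(filter_log, outp("filter_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  cdfs <- cdfs_general_model(X2, y, n_splits = cfgv("n_splits", 10),
                             keep_threshold = cfgv("keep_threshold", 0.95),
                             validation_fraction = cfgv("validation_fraction", 0.2),
                             seed = seed)
  utils::write.csv(cdfs_report(cdfs), outp("model_report.csv"),
                   row.names = FALSE)
  gm <- cdfs$general_model
  write_model_json(gm, outp("model_mlr.json"))

  ga_args <- cfgv("ga", list())
  ga_args$seed <- seed
  gaf <- ga_select(X2, y, do.call(ga_config, ga_args))
  write_model_json(gaf, outp("model_gapls.json"))
  utils::write.csv(gaf$trace, outp("ga_trace.csv"), row.names = FALSE)

  yr <- y_randomization(X2, y, gm$descriptors,
                        n_iter = cfgv("n_yrand", 10), seed = seed)
  utils::write.csv(yr, outp("y_randomization.csv"), row.names = FALSE)

  sp <- cdfs$final_split
  wt <- williams_table(gm, X2[sp$calibration, , drop = FALSE],
                       y[sp$calibration],
                       X2[sp$validation, , drop = FALSE], y[sp$validation])
  utils::write.csv(as.data.frame(wt), outp("williams.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tyroqsar")),
    seed = seed, n = nrow(X), p_raw = ncol(X), p_filtered = ncol(X2),
    general_model = gm$descriptors, gapls_model = gaf$descriptors,
    y_randomization_all_below = attr(yr, "all_below"),
    williams_h_star = attr(wt, "h_star"))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(cdfs = cdfs, gapls = gaf, y_randomization = yr,
                 williams = wt, manifest = manifest))
}

write_model_json <- function(model, path) {
  if (inherits(model, "qsar_lm")) {
    obj <- list(type = "mlr", descriptors = model$descriptors,
                coefficients = as.list(model$coefficients),
                se = as.list(model$se),
                stats = list(N = model$n, R2_c = model$r2_c,
                             S.E = model$sigma, Q2_LOO = model$q2_loo,
                             RMS_CV = model$rms_cv, R2_p = model$r2_p))
  } else if (inherits(model, "gapls_fit")) {
    obj <- list(type = "gapls", descriptors = model$descriptors,
                coefficients = as.list(coef(model$model)),
                n_components = model$model$n_components,
                stats = list(R2_c = model$model$r2_c,
                             Q2_LOO = model$q2_loo,
                             fitness = model$fitness))
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
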