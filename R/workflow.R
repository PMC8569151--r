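#' Pipeline configuration
#'
#' @param scene_paths three ASC band paths (red, green, blue).
#' @param fishnet_path GeoJSON fishnet path.
#' @param calibration a campaign label ("2017"/"2019"), a panel CSV path, or
#'   a calibration JSON path.
#' @param model_ids frozen model ids to apply.
#' @param truth_path optional ground-truth CSV (plot_id, lai, lg columns as
#'   available) enabling evaluation.
#' @param out_dir output directory (created if missing).
#' @param bit_depth sensor bits per channel.
#' @param seed integer seed recorded in the run manifest.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scene_paths, fishnet_path, calibration = "2017",
                            model_ids = c("reg1", "reg2", "reg3", "reg4"),
                            truth_path = NULL, out_dir = tempfile("run"),
                            bit_depth = 8L, seed = 1L) {
  structure(list(scene_paths = scene_paths, fishnet_path = fishnet_path,
                 calibration = calibration, model_ids = model_ids,
                 truth_path = truth_path, out_dir = out_dir,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "pipeline_config")
}

.resolve_calibration <- function(spec) {
  if (inherits(spec, "calibration_set")) return(spec)
  if (spec %in% c("2017", "2019")) return(builtin_calibrations(spec))
  if (!file.exists(spec)) stop(sprintf("calibration source not found: %s", spec))
  if (grepl("\\.json$", spec)) return(read_calibration_json(spec))
  fit_calibration_set(read_panel_csv(spec), label = spec)
}

.stage_log <- function(stage, n) {
  message(sprintf("[%s] %s: %d rows", format(Sys.time(), "%H:%M:%S"), stage, n))
}

#' Run the full estimation pipeline
#'
#' Extract zonal DN through the fishnet, calibrate to reflectance, compute
#' the six VIs, apply every requested frozen model, and (when ground truth is
#' supplied) evaluate each model. Writes \code{zonal.csv},
#' \code{reflectance.csv}, \code{vi.csv}, \code{estimates.csv}, optional
#' \code{metrics.json}, and a \code{manifest.json} recording seed and input
#' paths, all under \code{config$out_dir}.
#'
#' @param config a \code{pipeline_config}.
#' @return invisibly, a list with the estimates table and metrics (if any).
#' @export
run_estimation <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$scene_paths, config$fishnet_path))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  bad_ids <- setdiff(config$model_ids, c("reg1", "reg2", "reg3", "reg4"))
  if (length(bad_ids))
    stop(sprintf("unknown model id(s): %s", paste(bad_ids, collapse = ", ")))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  scene <- read_scene(config$scene_paths, bit_depth = config$bit_depth)
  net <- read_fishnet_geojson(config$fishnet_path)
  zonal <- zonal_mean_dn(scene, net)
  .stage_log("extract", nrow(zonal))
  bad <- zonal[!is.na(zonal$error), ]
  if (nrow(bad))
    stop(sprintf("zonal extraction failed for plot(s): %s",
                 paste(bad$plot_id, collapse = ", ")))
  utils::write.csv(zonal[, c("plot_id", "mean_dn_red", "mean_dn_green",
                             "mean_dn_blue", "pixel_count")],
                   file.path(config$out_dir, "zonal.csv"), row.names = FALSE,
                   quote = FALSE)

  cal <- .resolve_calibration(config$calibration)
  refl <- data.frame(
    plot_id = zonal$plot_id,
    red = suppressWarnings(apply_calibration(zonal$mean_dn_red, cal$red)),
    green = suppressWarnings(apply_calibration(zonal$mean_dn_green, cal$green)),
    blue = suppressWarnings(apply_calibration(zonal$mean_dn_blue, cal$blue)),
    stringsAsFactors = FALSE)
  .stage_log("calibrate", nrow(refl))
  utils::write.csv(refl, file.path(config$out_dir, "reflectance.csv"),
                   row.names = FALSE, quote = FALSE)

  vis <- vi_table(refl)
  .stage_log("indices", nrow(vis))
  utils::write.csv(vis[, c("plot_id", vi_names())],
                   file.path(config$out_dir, "vi.csv"), row.names = FALSE,
                   quote = FALSE)

  est_rows <- lapply(config$model_ids, function(id) {
    model <- frozen_model(id)
    est <- estimate_trait(vis, model)
    data.frame(plot_id = vis$plot_id, model = id, trait = model$trait,
               estimate = as.numeric(est),
               below_zero = attr(est, "below_zero"),
               stringsAsFactors = FALSE)
  })
  estimates <- do.call(rbind, est_rows)
  .stage_log("estimate", nrow(estimates))
  utils::write.csv(estimates, file.path(config$out_dir, "estimates.csv"),
                   row.names = FALSE, quote = FALSE)

  metrics <- NULL
  if (!is.null(config$truth_path)) {
    truth <- utils::read.csv(config$truth_path, stringsAsFactors = FALSE)
    metrics <- list()
    for (id in config$model_ids) {
      model <- frozen_model(id)
      tcol <- tolower(model$trait)
      if (!tcol %in% names(truth)) next
      sub <- merge(estimates[estimates$model == id, ],
                   truth[, c("plot_id", tcol)], by = "plot_id")
      vs <- validation_stats(sub[[tcol]], sub$estimate)
      metrics[[id]] <- list(trait = model$trait, n = nrow(sub),
                            mean_error = vs$mean_error,
                            sd_error = vs$sd_error, r2 = vs$r2)
    }
    .stage_log("evaluate", length(metrics))
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(
    list(seed = config$seed, scene_paths = config$scene_paths,
         fishnet_path = config$fishnet_path,
         calibration = if (inherits(config$calibration, "calibration_set"))
           config$calibration$label else config$calibration,
         model_ids = config$model_ids, n_plots = nrow(zonal)),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(estimates = estimates, metrics = metrics))
}

#' Train-on-one-campaign, validate-on-another
#'
#' Applies a model to a validation table and reports Table-6-style error
#' statistics. The model is either a frozen/linear model given directly, or
#' is refitted on \code{train_table} first.
#'
#' @param train_table training VI + trait table, or NULL to use \code{model}
#'   as given.
#' @param validation_table validation VI + trait table with the same VI
#'   schema.
#' @param model a \code{linear_trait_model} (e.g. \code{frozen_model("reg1")}).
#' @param refit if TRUE, refit the model's coefficients on
#'   \code{train_table} before validating.
#' @return a \code{validation_stats} object.
#' @export
run_validation <- function(train_table = NULL, validation_table, model,
                           refit = !is.null(train_table)) {
  stopifnot(inherits(model, "linear_trait_model"))
  need <- c(model$predictor_names, model$trait)
  missing_v <- setdiff(need, names(validation_table))
  if (length(missing_v))
    stop(sprintf("validation table lacks column(s): %s",
                 paste(missing_v, collapse = ", ")))
  if (refit) {
    missing_t <- setdiff(need, names(train_table))
    if (length(missing_t))
      stop(sprintf("training table lacks column(s): %s",
                   paste(missing_t, collapse = ", ")))
    model <- fit_linear_trait_model(train_table, model$trait,
                                    model$predictor_names, model$mode)
  }
  pred <- as.numeric(estimate_trait(validation_table, model))
  validation_stats(validation_table[[model$trait]], pred)
}
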