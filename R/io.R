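## provenance header written at the top of every output CSV
provenance_header <- function(seed = NULL, extra = NULL) {
  h <- c(paste0("# written by catIAM ",
                as.character(utils::packageVersion("catIAM"))),
         if (!is.null(seed)) paste0("# seed: ", seed),
         if (!is.null(extra)) paste0("# ", names(extra), ": ", unlist(extra)))
  h
}

write_csv_with_header <- function(df, path, seed = NULL, extra = NULL,
                                  overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("refusing to overwrite existing file ", path,
         " (use overwrite = TRUE)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read geo-referenced sighting records
#'
#' Reads a sightings CSV with columns `record_id`, `observer_type`
#' (`survey`/`report`/`expert`), `x`, `y`, `crs` (`metres` or `wgs84`),
#' `raw_value` (a survey category for surveys, a non-negative count
#' otherwise) and `study_area`. Lines starting with `#` are treated as
#' comments. Validation errors name the offending (1-based, header excluded)
#' data row.
#'
#' @param path CSV file path.
#' @return data.frame of validated sighting records.
#' @export
read_sightings <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("record_id", "observer_type", "x", "y", "crs", "raw_value",
            "study_area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sightings file lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!df$observer_type %in% c("survey", "report", "expert"))
  if (length(bad)) {
    stop("unknown observer_type ", sQuote(df$observer_type[bad[1]]),
         " at row ", bad[1])
  }
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("unparseable coordinate ", sQuote(df[[cc]][bad[1]]), " in column ",
           cc, " at row ", bad[1])
    }
    df[[cc]] <- v
  }
  num <- df$observer_type != "survey" | grepl("^[0-9.]+$", df$raw_value)
  v <- suppressWarnings(as.numeric(df$raw_value))
  bad <- which(num & (!is.finite(v) | v < 0) & df$observer_type != "survey")
  if (length(bad)) {
    stop("negative or unparseable count ", sQuote(df$raw_value[bad[1]]),
         " at row ", bad[1])
  }
  df
}

#' Write sighting records
#' @param records data.frame in the [read_sightings()] schema.
#' @param path output CSV path.
#' @param seed seed recorded in the provenance header.
#' @param overwrite overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_sightings <- function(records, path, seed = NULL, overwrite = FALSE) {
  write_csv_with_header(records, path, seed = seed, overwrite = overwrite)
}

#' Read a small-area statistics table
#'
#' Reads an areas CSV with columns `area_id`, `country`, an IMD column
#' (`imd_decile` on 1-10 or `imd_quintile` on 1-5, auto-detected),
#' `pop_density` (people per km2, >= 0) and `land_area` (km2, > 0).
#'
#' @param path CSV file path.
#' @return data.frame of validated areas, with the detected scale in
#'   `attr(, "imd_scale")`.
#' @export
read_areas <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("area_id", "country", "pop_density", "land_area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("areas file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if ("imd_decile" %in% names(df)) {
    scale <- "decile"; rng <- c(1, 10); col <- "imd_decile"
  } else if ("imd_quintile" %in% names(df)) {
    scale <- "quintile"; rng <- c(1, 5); col <- "imd_quintile"
  } else {
    stop("areas file needs an imd_decile or imd_quintile column")
  }
  bad <- which(!is.finite(df[[col]]) | df[[col]] < rng[1] | df[[col]] > rng[2])
  if (length(bad)) {
    stop(col, " value ", df[[col]][bad[1]], " out of range [", rng[1], ", ",
         rng[2], "] at row ", bad[1])
  }
  bad <- which(!is.finite(df$pop_density) | df$pop_density < 0)
  if (length(bad)) stop("invalid pop_density at row ", bad[1])
  bad <- which(!is.finite(df$land_area) | df$land_area <= 0)
  if (length(bad)) stop("invalid land_area at row ", bad[1])
  attr(df, "imd_scale") <- scale
  df
}

#' Write a small-area statistics table
#' @param areas data.frame in the [read_areas()] schema.
#' @param path output CSV path.
#' @param seed seed recorded in the provenance header.
#' @param overwrite overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_areas <- function(areas, path, seed = NULL, overwrite = FALSE) {
  write_csv_with_header(areas, path, seed = seed, overwrite = overwrite)
}

#' Write posterior draws as tidy CSV
#'
#' One row per (chain, iteration, parameter, value), plus a summary CSV
#' alongside if `summary_path` is given.
#'
#' @param fit an `iam_fit`.
#' @param path output CSV path.
#' @param summary_path optional path for the parameter summary table.
#' @param overwrite overwrite existing files?
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path, summary_path = NULL,
                            overwrite = FALSE) {
  stopifnot(inherits(fit, "iam_fit"))
  d <- fit$draws
  tidy <- data.frame(chain = rep(fit$chain, ncol(d)),
                     iteration = rep(fit$iteration, ncol(d)),
                     parameter = rep(colnames(d), each = nrow(d)),
                     value = as.vector(d))
  extra <- list(rhat_max = if (!is.null(fit$rhat)) max(fit$rhat) else NA)
  write_csv_with_header(tidy, path, seed = fit$seed, extra = extra,
                        overwrite = overwrite)
  if (!is.null(summary_path)) {
    write_csv_with_header(posterior_summary(fit), summary_path,
                          seed = fit$seed, extra = extra,
                          overwrite = overwrite)
  }
  invisible(path)
}

#' Run the full pipeline: simulate, cluster, fit, predict
#'
#' Thin orchestration over the package's stages with provenance logging.
#' The configuration is a named list (or a YAML file path) with optional
#' sections `truth` (arguments to [truth_config()]), `model` (arguments to
#' [model_config()]), `mcmc` (arguments to [mcmc_config()]), `prediction`
#' (arguments to [prediction_config()]), `areas` (arguments to
#' [make_area_table()] or a path to an areas CSV) and a global `seed`.
#' Stages: simulate a dataset (with raw sighting points), cluster the points
#' back into sites, fit the model, project onto the area table. Each stage
#' failure halts with a stage-named message. Outputs (sightings, sites
#' summary, posterior draws, predictions, aggregates) are written under
#' `out_dir` with seed-carrying headers.
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory (created if needed).
#' @param overwrite overwrite existing outputs?
#' @return List with the fitted model, prediction, and output paths,
#'   invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("catiam_"),
                         overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  truth <- stage("simulate",
                 do.call(truth_config, c(config$truth, list(seed = seed))))
  sim <- stage("simulate", simulate_sites(truth, points = TRUE))
  p_sight <- file.path(out_dir, "sightings.csv")
  write_sightings(sim$sightings, p_sight, seed = seed, overwrite = overwrite)

  assign_ <- stage("cluster", cluster_sightings(sim$sightings,
                                                radius_m = config$radius_m %||% 500))
  ## site covariates: each recovered cluster inherits the covariates of the
  ## generating site of its first member (clusters match sites one-to-one,
  ## the simulated layout spaces sites far beyond the clustering radius)
  true_site <- attr(sim$sightings, "site_index")
  ids <- sort(unique(assign_))
  cov_tab <- cbind(data.frame(site_id = ids),
                   as.data.frame(sim$truth$X[
                     true_site[match(ids, assign_)], , drop = FALSE]))
  sites <- stage("cluster", build_site_data(sim$sightings, assign_, cov_tab))

  model <- stage("fit", do.call(model_config,
                                c(config$model %||%
                                    list(covariates = names(truth$beta)))))
  mcmc <- stage("fit", do.call(mcmc_config,
                               c(config$mcmc %||% list(preset = "reduced"),
                                 list(seed = seed))))
  fit <- stage("fit", fit_iam(sites, model, mcmc))
  write_posterior(fit, file.path(out_dir, "posterior.csv"),
                  file.path(out_dir, "posterior_summary.csv"),
                  overwrite = overwrite)

  pred <- NULL
  if (!is.null(config$areas)) {
    areas <- stage("predict", if (is.character(config$areas)) {
      read_areas(config$areas)
    } else {
      do.call(make_area_table, c(config$areas, list(seed = seed)))
    })
    pcfg <- stage("predict", do.call(prediction_config,
                                     config$prediction %||% list()))
    pd <- stage("predict", predict_area(fit, areas, pcfg))
    pred <- stage("predict", aggregate_predictions(pd))
    write_csv_with_header(pred$per_area,
                          file.path(out_dir, "predictions.csv"),
                          seed = seed, overwrite = overwrite)
    write_csv_with_header(pred$aggregate,
                          file.path(out_dir, "aggregates.csv"),
                          seed = seed, overwrite = overwrite)
  }
  invisible(list(fit = fit, prediction = pred, sites = sites,
                 out_dir = out_dir,
                 paths = list.files(out_dir, full.names = TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
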