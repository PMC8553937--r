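#' Configuration for small-area abundance projection
#'
#' @param density_cap truncation limit for human population density, in
#'   people per km2 on the raw scale (default 15,129, the highest density in
#'   the fitted site network). Densities above the cap contribute the capped
#'   value, a conservative choice that stops extrapolation beyond the fitted
#'   range.
#' @param reference_site_area_km2 site area implied by the fitted model's
#'   site definition, used in the scaling parameter SP = land_area /
#'   reference area. Default 0.2 km2 (the 20 ha assumed maximum home range
#'   that defined the clustering radius).
#' @param density_scaler a `cov_scaler` from [standardize_covariate()]
#'   holding the *fitting* data's density mean/SD, so new areas standardize
#'   against the fitted scale. `NULL` means densities are already on the
#'   fitted (standardized) scale.
#' @param imd_covariate,density_covariate names of the IMD and density
#'   coefficients in the fit (without the `beta_` prefix).
#' @param imd_scale `"decile"` or `"quintile"`; must match the scale the
#'   model was fitted on (no decile-to-quintile coefficient conversion is
#'   attempted).
#' @param lognormal_correction if `TRUE`, multiply predictions by
#'   `exp(sigma^2/2)` per draw. Off by default: the projection formula is the
#'   literal log-linear mean without the site random effect or occupancy.
#' @return List of class `prediction_config`.
#' @export
prediction_config <- function(density_cap = 15129,
                              reference_site_area_km2 = 0.2,
                              density_scaler = NULL,
                              imd_covariate = "imd",
                              density_covariate = "popdens",
                              imd_scale = c("decile", "quintile"),
                              lognormal_correction = FALSE) {
  imd_scale <- match.arg(imd_scale)
  stopifnot(density_cap > 0, reference_site_area_km2 > 0)
  if (!is.null(density_scaler)) stopifnot(inherits(density_scaler, "cov_scaler"))
  structure(list(density_cap = density_cap,
                 reference_site_area_km2 = reference_site_area_km2,
                 density_scaler = density_scaler,
                 imd_covariate = imd_covariate,
                 density_covariate = density_covariate,
                 imd_scale = imd_scale,
                 lognormal_correction = lognormal_correction),
            class = "prediction_config")
}

#' Project posterior abundance onto small areas
#'
#' Applies the posterior draws of the intercept and effect sizes to an area
#' covariate table: for retained draw d and area a,
#' `abundance_{d,a} = exp(mu_d + beta_IMD,d * IMD_a + beta_PD,d *
#' min(PD_a, cap)) * SP_a`, where PD is standardized against the fitting
#' data, the cap is the truncation limit on the standardized scale, and
#' `SP_a = land_area_a / reference_site_area` scales site-level abundance to
#' the area's size. Areas with missing covariates are excluded with a
#' warning.
#'
#' @param fit an `iam_fit` whose model includes the IMD and density
#'   covariates, or a data.frame/matrix of draws with columns `mu`,
#'   `beta_<imd>`, `beta_<density>` (and `sigma` if the lognormal correction
#'   is on).
#' @param areas data.frame of areas ([make_area_table()] / [read_areas()]
#'   schema): `area_id`, `country`, `imd_decile` or `imd_quintile`,
#'   `pop_density`, `land_area`.
#' @param config a [prediction_config()].
#' @return Object of class `iam_prediction_draws`: a draws x areas matrix of
#'   abundances with the (possibly filtered) `areas` attached as an
#'   attribute.
#' @export
predict_area <- function(fit, areas, config = prediction_config()) {
  stopifnot(inherits(config, "prediction_config"))
  draws <- if (inherits(fit, "iam_fit")) fit$draws else as.matrix(fit)
  bi <- paste0("beta_", config$imd_covariate)
  bd <- paste0("beta_", config$density_covariate)
  need <- c("mu", bi, bd)
  if (!all(need %in% colnames(draws))) {
    stop("draws lack column(s): ",
         paste(setdiff(need, colnames(draws)), collapse = ", "))
  }
  imd_col <- paste0("imd_", config$imd_scale)
  stopifnot(all(c(imd_col, "pop_density", "land_area") %in% names(areas)))
  ok <- stats::complete.cases(areas[, c(imd_col, "pop_density", "land_area")])
  if (any(!ok)) {
    warning("excluding ", sum(!ok), " area(s) with missing covariates")
    areas <- areas[ok, , drop = FALSE]
  }
  pd <- areas$pop_density
  cap <- config$density_cap
  if (!is.null(config$density_scaler)) {
    pd <- apply_scaler(pd, config$density_scaler)
    cap <- apply_scaler(cap, config$density_scaler)
  }
  pd <- pmin(pd, cap)
  sp <- areas$land_area / config$reference_site_area_km2
  lin <- outer(draws[, bi], areas[[imd_col]]) + outer(draws[, bd], pd)
  ab <- exp(draws[, "mu"] + lin)
  if (config$lognormal_correction) {
    if (!"sigma" %in% colnames(draws)) {
      stop("lognormal correction needs sigma draws")
    }
    ab <- ab * exp(draws[, "sigma"]^2 / 2)
  }
  ab <- sweep(ab, 2, sp, `*`)
  colnames(ab) <- areas$area_id
  structure(ab, areas = areas, class = c("iam_prediction_draws", "matrix"))
}

#' Aggregate per-area abundance draws to groups and totals
#'
#' Totals are formed draw-wise first (sum across areas within each retained
#' draw) and only then summarized, so aggregate credible intervals carry the
#' full joint posterior uncertainty rather than naive sums of interval
#' endpoints.
#'
#' @param pred an `iam_prediction_draws` matrix from [predict_area()], or any
#'   draws x areas matrix.
#' @param areas area table matching the columns of `pred` (taken from the
#'   prediction attribute if omitted).
#' @param by name of the grouping column in `areas` (default `"country"`).
#' @return Object of class `iam_prediction`: list with `per_area`
#'   (mean/CRI/density per area), `aggregate` (one row per group plus a
#'   `Total` row), and `draw_totals` (per-draw group totals, groups in
#'   columns).
#' @export
aggregate_predictions <- function(pred, areas = NULL, by = "country") {
  if (is.null(areas)) areas <- attr(pred, "areas")
  stopifnot(!is.null(areas), ncol(pred) == nrow(areas))
  summ <- function(m) {
    data.frame(mean = colMeans(m),
               lower95 = apply(m, 2, stats::quantile, 0.025),
               upper95 = apply(m, 2, stats::quantile, 0.975))
  }
  per_area <- cbind(data.frame(area_id = areas$area_id), summ(pred))
  per_area$density_mean <- per_area$mean / areas$land_area
  rownames(per_area) <- NULL
  g <- as.character(areas[[by]])
  groups <- unique(g)
  draw_totals <- vapply(groups, function(gr) {
    rowSums(pred[, g == gr, drop = FALSE])
  }, numeric(nrow(pred)))
  total <- rowSums(draw_totals)
  agg <- cbind(data.frame(group = c(groups, "Total"),
                          land_km2 = c(vapply(groups, function(gr) {
                            sum(areas$land_area[g == gr])
                          }, 0), sum(areas$land_area))),
               summ(cbind(draw_totals, Total = total)))
  rownames(agg) <- NULL
  structure(list(per_area = per_area, aggregate = agg,
                 draw_totals = cbind(draw_totals, Total = total),
                 areas = areas),
            class = "iam_prediction")
}

#' @export
print.iam_prediction <- function(x, ...) {
  cat("<iam_prediction> ", nrow(x$per_area), " areas\n", sep = "")
  print(x$aggregate, digits = 6)
  invisible(x)
}

#' Density statistics of a projection
#'
#' Per-area mean density (abundance / land area, per km2) and the median
#' across areas of those means — the headline "typical density" figure.
#'
#' @param result an `iam_prediction` from [aggregate_predictions()].
#' @return List with `per_area` (`area_id`, `density_mean`) and
#'   `median_density`.
#' @export
density_summary <- function(result) {
  stopifnot(inherits(result, "iam_prediction"))
  list(per_area = result$per_area[, c("area_id", "density_mean")],
       median_density = stats::median(result$per_area$density_mean))
}

#' Validate projected densities against reference estimates
#'
#' Compares projected per-area densities with reference (e.g. raw-data
#' model-derived) density estimates at matched areas: the fraction of
#' predictions falling inside the reference 95% credible intervals, and the
#' Spearman rank correlation of the means.
#'
#' @param predicted data.frame with `area_id` and `mean` (predicted density
#'   or abundance per area).
#' @param reference data.frame with `area_id`, `mean`, `lower95`, `upper95`.
#' @return List with `overlap` (fraction inside reference CRIs), `rho`
#'   (Spearman), `p_value`, `n_matched`.
#' @export
prediction_validation <- function(predicted, reference) {
  m <- match(predicted$area_id, reference$area_id)
  keep <- !is.na(m)
  if (!any(keep)) stop("no matched area identifiers")
  p <- predicted[keep, ]; r <- reference[m[keep], ]
  overlap <- mean(p$mean >= r$lower95 & p$mean <= r$upper95)
  ct <- suppressWarnings(stats::cor.test(p$mean, r$mean, method = "spearman"))
  list(overlap = overlap, rho = unname(ct$estimate),
       p_value = ct$p.value, n_matched = sum(keep))
}
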