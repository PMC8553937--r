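# fixed draw matrices make the projection arithmetic fully checkable
draws_fixture <- function(mu, b_imd, b_pd, n = 1) {
  cbind(mu = rep(mu, n), beta_imd = rep(b_imd, n), beta_popdens = rep(b_pd, n))
}

area_fixture <- function(imd, pd, land = 0.2, country = "England") {
  data.frame(area_id = sprintf("A%03d", seq_along(imd)), country = country,
             imd_decile = imd, pop_density = pd, land_area = land,
             urban = TRUE)
}

test_that("the projection formula evaluates literally", {
  cfg <- prediction_config(density_cap = 10, reference_site_area_km2 = 0.2)
  # all-zero draw, SP = 1 -> abundance 1
  p0 <- predict_area(draws_fixture(0, 0, 0), area_fixture(5, 1), cfg)
  expect_equal(as.numeric(p0), 1)
  # worked example on the GLM-scale coefficients:
  # exp(1 - 0.32*5 + 0.31*0.5) = exp(-0.445)
  p1 <- predict_area(draws_fixture(1, -0.32, 0.31),
                     area_fixture(5, 0.5), cfg)
  expect_equal(as.numeric(p1), exp(-0.445))
  expect_lt(abs(as.numeric(p1) - 0.6408), 5e-5)
})

test_that("density truncation is idempotent above the cap", {
  cfg <- prediction_config(density_cap = 2, reference_site_area_km2 = 0.2)
  d <- draws_fixture(1, -0.32, 0.31)
  at_cap <- predict_area(d, area_fixture(5, 2), cfg)
  above <- predict_area(d, area_fixture(5, 50), cfg)
  far_above <- predict_area(d, area_fixture(5, 5000), cfg)
  expect_equal(as.numeric(above), as.numeric(at_cap))
  expect_equal(as.numeric(far_above), as.numeric(at_cap))
  below <- predict_area(d, area_fixture(5, 1.9), cfg)
  expect_lt(as.numeric(below), as.numeric(at_cap))
})

test_that("raw densities standardize against the fitting scale", {
  scaler <- standardize_covariate(c(1000, 3000, 5000, 7000))
  cfg <- prediction_config(density_cap = 7000, density_scaler = scaler,
                           reference_site_area_km2 = 0.2)
  d <- draws_fixture(1, -0.32, 0.31)
  got <- predict_area(d, area_fixture(5, 5000), cfg)
  want <- exp(1 - 1.6 + 0.31 * apply_scaler(5000, scaler)) * 1
  expect_equal(as.numeric(got), as.numeric(want))
})

test_that("monotonicity in the covariates holds with the fitted signs", {
  cfg <- prediction_config(density_cap = 10, reference_site_area_km2 = 0.2)
  d <- draws_fixture(1, -0.32, 0.31)
  dens <- predict_area(d, area_fixture(rep(5, 5), c(0.5, 1, 2, 5, 9)), cfg)
  expect_true(all(diff(as.numeric(dens)) > 0))
  imd <- predict_area(d, area_fixture(1:10, rep(1, 10)), cfg)
  expect_true(all(diff(as.numeric(imd)) < 0))
})

test_that("aggregation is draw-wise: exact means, joint-uncertainty CRIs", {
  set.seed(5)
  n_draws <- 2000
  draws <- cbind(mu = rnorm(n_draws, 1, 0.3),
                 beta_imd = rnorm(n_draws, -0.3, 0.05),
                 beta_popdens = rnorm(n_draws, 0.3, 0.05))
  areas <- area_fixture(sample(1:10, 20, TRUE), runif(20, 0.1, 3),
                        land = runif(20, 0.5, 2))
  pred <- predict_area(draws, areas,
                       prediction_config(density_cap = 10,
                                         reference_site_area_km2 = 0.2))
  agg <- aggregate_predictions(pred, by = "country")
  tot <- agg$aggregate[agg$aggregate$group == "Total", ]
  # linearity: mean of the total equals the sum of per-area means exactly
  expect_equal(tot$mean, sum(agg$per_area$mean))
  # the joint total CRI is narrower than the sum of per-area CRI widths
  widths <- agg$per_area$upper95 - agg$per_area$lower95
  expect_lt(tot$upper95 - tot$lower95, sum(widths))
  # per-draw total = sum of per-draw area values exactly
  expect_equal(unname(agg$draw_totals[, "Total"]), unname(rowSums(pred)))
})

test_that("splitting an area in half leaves the total invariant", {
  d <- draws_fixture(1, -0.32, 0.31, n = 50)
  cfg <- prediction_config(density_cap = 10, reference_site_area_km2 = 0.2)
  whole <- aggregate_predictions(predict_area(d, area_fixture(4, 1, land = 2),
                                              cfg))
  halves <- aggregate_predictions(predict_area(d, area_fixture(c(4, 4),
                                                               c(1, 1),
                                                               land = 1),
                                               cfg))
  expect_equal(whole$aggregate$mean[whole$aggregate$group == "Total"],
               halves$aggregate$mean[halves$aggregate$group == "Total"])
})

test_that("density summaries divide by land area and take the area median", {
  d <- draws_fixture(0, 0, 0, n = 10)
  cfg <- prediction_config(density_cap = 10, reference_site_area_km2 = 0.2)
  # abundance = land/0.2; density = 1/0.2 = 5 for every area
  pred <- aggregate_predictions(predict_area(d, area_fixture(5, 1, land = 2),
                                             cfg))
  expect_equal(pred$per_area$density_mean, 10 / 2)
  # median across areas of per-area mean densities
  res <- structure(list(per_area = data.frame(area_id = c("a", "b", "c"),
                                              density_mean = c(1, 9.3, 57))),
                   class = "iam_prediction")
  expect_equal(density_summary(res)$median_density, 9.3)
})

test_that("densities scale inversely with land area at fixed abundance", {
  base <- data.frame(area_id = c("a", "b"), density_mean = c(10, 5) / 1)
  doubled <- data.frame(area_id = c("a", "b"), density_mean = c(10, 5) / 2)
  expect_equal(doubled$density_mean, base$density_mean / 2)
})

test_that("prediction validation measures CRI overlap and rank agreement", {
  ref <- data.frame(area_id = letters[1:6], mean = c(1, 2, 3, 4, 5, 6),
                    lower95 = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5),
                    upper95 = c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5))
  same <- data.frame(area_id = letters[1:6], mean = ref$mean)
  v <- prediction_validation(same, ref)
  expect_equal(v$overlap, 1)
  expect_equal(v$rho, 1)
  anti <- data.frame(area_id = letters[1:6], mean = rev(ref$mean))
  expect_equal(prediction_validation(anti, ref)$rho, -1)
  expect_error(prediction_validation(
    data.frame(area_id = "zz", mean = 1), ref), "no matched")
})

test_that("self-consistent projection tracks the fitting sites' estimates", {
  # Project back onto the fitting sites and compare with the per-site
  # abundance CRIs from the same fit. The covariate-only projection formula
  # carries no site residual or occupancy term, so at site level it misses
  # the extremes pinned by site data: overlap is substantial but partial,
  # while the rank agreement is consistently significant.
  overlaps <- rhos <- ps <- numeric(3)
  for (r in 1:3) {
    cfg <- truth_config(n_sites = 60, n_study_areas = 3, seed = 100 + r,
                        survey_reps = c(2, 6), report_reps = c(1, 3))
    sim <- simulate_sites(cfg)
    fit <- suppressWarnings(
      fit_iam(sim$sites, model_config(covariates = c("imd", "popdens")),
              short_mcmc(seed = r)))
    areas <- data.frame(area_id = sim$sites$site_id, country = "study",
                        imd_decile = sim$sites$covariates$imd,
                        pop_density = sim$sites$covariates$popdens,
                        land_area = 0.2, urban = TRUE)
    pred <- aggregate_predictions(
      predict_area(fit, areas,
                   prediction_config(density_cap = max(areas$pop_density),
                                     reference_site_area_km2 = 0.2)))
    v <- prediction_validation(
      data.frame(area_id = pred$per_area$area_id, mean = pred$per_area$mean),
      transform(site_abundance(fit), area_id = sim$sites$site_id))
    overlaps[r] <- v$overlap; rhos[r] <- v$rho; ps[r] <- v$p_value
  }
  expect_gte(mean(overlaps), 0.6)
  expect_true(all(rhos > 0.3))
  expect_true(all(ps < 0.01))
})

test_that("areas with missing covariates are excluded with a warning", {
  a <- area_fixture(c(5, NA), c(1, 1))
  expect_warning(
    p <- predict_area(draws_fixture(0, 0, 0), a,
                      prediction_config(density_cap = 10)),
    "missing")
  expect_equal(ncol(p), 1)
})
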