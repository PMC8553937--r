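test_that("Gelman-Rubin statistic matches its defining cases", {
  set.seed(1)
  x <- rnorm(500)
  expect_equal(gelman_rubin(cbind(x, x)), sqrt(499 / 500))

  set.seed(2)
  big <- matrix(rnorm(20000), ncol = 2)
  expect_lt(abs(gelman_rubin(big) - 1), 0.01)

  apart <- cbind(rnorm(200, 0), rnorm(200, 10))
  expect_gt(gelman_rubin(apart), 2)

  # one flat chain among varying ones is still defined
  expect_true(is.finite(gelman_rubin(cbind(rep(1, 100), rnorm(100)))))
  # fully constant chains return the degenerate identical-chain value
  expect_equal(gelman_rubin(cbind(rep(2, 50), rep(2, 50))), sqrt(49 / 50))
  expect_error(gelman_rubin(matrix(1:20, ncol = 1)), "2 chains")
})

test_that("effect probabilities are sign fractions of the posterior", {
  expect_equal(effect_probability(c(-1, 2, 3, 4), "positive"), 0.75)
  expect_equal(effect_probability(c(-1, -2, -0.5), "negative"), 1.0)
  set.seed(3)
  sym <- rnorm(100000)
  expect_lt(abs(effect_probability(sym, "positive") - 0.5), 0.01)
})

test_that("variance explained is the proportional sigma^2 reduction", {
  d <- runif(1000, 0.5, 1.5)
  expect_equal(variance_explained(d, d), 0)
  expect_equal(variance_explained(rep(1, 1000), rep(sqrt(0.63), 1000)), 0.37)
  # an inflated covariate-model variance goes negative, unclamped
  expect_lt(variance_explained(rep(1, 100), rep(1.2, 100)), 0)
  expect_error(variance_explained(rep(0, 10), rep(1, 10)), "positive")
})

test_that("quasi-Poisson screening recovers a noiseless log-linear law", {
  x <- 0:9
  resp <- exp(1 + 2 * x)
  tab <- glm_screen(resp, data.frame(x = x))
  expect_lt(abs(tab$estimate[tab$term == "(Intercept)"] - 1), 1e-6)
  expect_lt(abs(tab$estimate[tab$term == "x"] - 2), 1e-6)
})

test_that("quasi-Poisson screening is calibrated on Poisson simulations", {
  hits <- logical(20); disp <- numeric(20)
  for (r in 1:20) {
    set.seed(400 + r)
    x <- rnorm(500)
    yv <- rpois(500, exp(1 + 0.31 * x))
    tab <- glm_screen(yv, data.frame(x = x))
    est <- tab$estimate[tab$term == "x"]
    se <- tab$std_error[tab$term == "x"]
    hits[r] <- abs(est - 0.31) <= 2 * se
    disp[r] <- attr(tab, "dispersion")
  }
  expect_gte(mean(hits), 0.95)
  # Pearson dispersion of pure-Poisson data sits near 1
  expect_lt(abs(mean(disp) - 1), 0.05)
})

test_that("leave-one-area-out folds partition the sites", {
  sim <- small_sim(seed = 51, n_sites = 40)
  cv <- suppressWarnings(
    crossvalidate_by_area(sim$sites, model_config(covariates = c("imd", "popdens")),
                          short_mcmc(seed = 9)))
  areas <- unique(sim$sites$study_area)
  expect_equal(length(cv$folds), length(areas))
  n_by_fold <- vapply(cv$folds, function(f) f$sites$n_sites, 0)
  n_area <- as.vector(table(sim$sites$study_area)[areas])
  # each fold excludes exactly its area's sites; fold counts sum accordingly
  expect_equal(unname(n_by_fold[areas]), sim$sites$n_sites - n_area)
  for (a in areas) {
    expect_false(a %in% cv$folds[[a]]$sites$study_area)
  }
  # on this simulated truth every fold's beta CRI covers the true effects
  bi <- cv$table[cv$table$parameter == "beta_imd", ]
  expect_true(all(bi$lower95 <= -0.32 & -0.32 <= bi$upper95))
})

test_that("single-source refits keep expert data and count retained sites", {
  sim <- small_sim(seed = 61, n_sites = 50)
  # thin some sources so the retained-site counts differ
  s <- sim$sites
  drop_sv <- c(2, 9); drop_rp <- c(4, 5, 12)
  for (i in drop_sv) s$survey_counts[[i]] <- numeric(0)
  for (i in drop_rp) s$report_counts[[i]] <- numeric(0)
  keepable <- lengths(s$survey_counts) + lengths(s$report_counts) > 0
  s <- s[keepable]
  res <- suppressWarnings(
    single_source_refits(s, model_config(covariates = c("imd", "popdens")),
                         short_mcmc(seed = 13)))
  expect_equal(res$variants$survey_only$n_sites,
               sum(lengths(s$survey_counts) > 0))
  expect_equal(res$variants$report_only$n_sites,
               sum(lengths(s$report_counts) > 0))
  # expert data at retained sites are untouched
  kept <- match(res$variants$survey_only$site_id, s$site_id)
  expect_identical(res$variants$survey_only$expert_count, s$expert_count[kept])
  # both variants recover the signs of the generating effects
  tab <- res$table
  expect_true(all(tab$mean[tab$parameter == "beta_imd"] < 0))
  expect_true(all(tab$mean[tab$parameter == "beta_popdens"] > 0))
})

test_that("coefficient posteriors are insensitive to wide priors and pile
          up against over-narrow ones", {
  sim <- small_sim(seed = 71, n_sites = 60)
  ps <- suppressWarnings(
    prior_sensitivity(sim$sites, model_config(covariates = c("imd", "popdens")),
                      short_mcmc(seed = 21), widths = c(5, 10)))
  tab <- ps$table
  # posterior support always inside the prior bounds
  expect_true(all(abs(tab$lower95) <= tab$prior_halfwidth))
  expect_true(all(abs(tab$upper95) <= tab$prior_halfwidth))
  # widths 5 and 10 agree within Monte-Carlo error
  for (p in unique(tab$parameter)) {
    d <- tab[tab$parameter == p, ]
    expect_lt(abs(diff(d$mean)), 0.1)
    expect_false(any(d$truncated))
  }

  # a strong true effect against a +/-0.5 prior truncates visibly
  strong <- simulate_sites(truth_config(n_sites = 50, mu = 1.2,
                                        beta = c(popdens = 1), sigma = 0.4,
                                        seed = 5))
  narrow <- suppressWarnings(
    prior_sensitivity(strong$sites, model_config(covariates = "popdens"),
                      short_mcmc(seed = 22), widths = 0.5))
  expect_true(all(narrow$table$truncated))
})

test_that("simulation recovery reports coverage, bias and convergence", {
  cfg <- truth_config(n_sites = 40, n_study_areas = 2, seed = 81,
                      survey_reps = c(3, 10), report_reps = c(1, 5))
  rec <- simulation_recovery(cfg, n_reps = 10,
                             mcmc = mcmc_config(n_chains = 2, n_iter = 1500,
                                                burn_in = 500, seed = 30))
  expect_true(all(rec$table$coverage >= 0 & rec$table$coverage <= 1))
  expect_true(all(rec$table$coverage_se >= 0))
  expect_equal(rec$table$n_reps, rep(10, nrow(rec$table)))
  expect_true(all(c("covered", "converged") %in% names(rec$details)))
  # non-converged replicates are reported in the details, never dropped
  expect_equal(nrow(rec$details), 10 * nrow(rec$table))
})

test_that("full expert coverage reduces detection-probability bias", {
  base <- truth_config(n_sites = 40, n_study_areas = 2, seed = 91,
                       survey_reps = c(3, 10), report_reps = c(1, 5))
  full <- base; full$expert_coverage <- 1
  sparse <- base; sparse$expert_coverage <- 0.2
  mc <- mcmc_config(n_chains = 2, n_iter = 1500, burn_in = 500, seed = 40)
  rec_full <- simulation_recovery(full, n_reps = 10, mcmc = mc,
                                  parameters = "p_survey")
  rec_sparse <- simulation_recovery(sparse, n_reps = 10, mcmc = mc,
                                    parameters = "p_survey")
  expect_lt(abs(rec_full$table$bias), abs(rec_sparse$table$bias))
})
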