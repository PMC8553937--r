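#' Gelman-Rubin potential scale reduction factor
#'
#' Convergence diagnostic comparing between- and within-chain variance for
#' one scalar parameter. With m chains of length n, chain means `xbar_c` and
#' within-chain variances `s2_c`:
#' `W = mean(s2_c)`, `B/n = var(xbar_c)`, and
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Values below 1.1 are read as
#' convergence. Identical chains give `sqrt((n-1)/n)` (also returned in the
#' fully degenerate all-constant case); chains with no within-chain variance
#' but different means give `Inf`.
#'
#' @param chains a numeric matrix (rows = iterations, columns = chains) or a
#'   list of equal-length numeric vectors; at least 2 chains of length >= 10.
#' @return The potential scale reduction factor (a single number).
#' @export
#' @examples
#' x <- rnorm(1000)
#' gelman_rubin(cbind(x, x))  # sqrt(999/1000)
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1) {
      stop("all chains must have equal length")
    }
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need chains of length >= 10")
  W <- mean(apply(chains, 2, stats::var))
  B_over_n <- stats::var(colMeans(chains))
  if (W == 0) {
    if (B_over_n == 0) return(sqrt((n - 1) / n))
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Posterior probability of a covariate effect's sign
#'
#' The fraction of posterior draws of a regression coefficient with the
#' stated sign: `P(beta > 0)` or `P(beta < 0)`, the model-based credibility
#' of a positive or negative covariate effect.
#'
#' @param draws numeric vector of posterior draws, or an `iam_fit` together
#'   with `parameter`.
#' @param direction `"positive"` or `"negative"`.
#' @param parameter column name when `draws` is an `iam_fit`.
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' effect_probability(c(-1, 2, 3, 4), "positive")  # 0.75
effect_probability <- function(draws, direction = c("positive", "negative"),
                               parameter = NULL) {
  direction <- match.arg(direction)
  if (inherits(draws, "iam_fit")) {
    if (is.null(parameter)) stop("give the parameter name for an iam_fit")
    if (!parameter %in% colnames(draws$draws)) {
      stop("unknown parameter name: ", parameter)
    }
    draws <- draws$draws[, parameter]
  }
  if (direction == "positive") mean(draws > 0) else mean(draws < 0)
}

#' Proportion of site-level variance explained by covariates
#'
#' The proportional reduction in the residual site-specific log-abundance
#' variance when covariates are added to the null (random-effects only)
#' model: `1 - E[sigma^2_cov] / E[sigma^2_null]`, with expectations over the
#' retained posterior draws. Posterior means of sigma^2 are the default
#' functional; posterior medians are available as an option. A covariate
#' model with *larger* residual variance yields a negative value (not
#' clamped).
#'
#' @param null_sigma_draws posterior draws of sigma from the null model (or a
#'   null-model `iam_fit`).
#' @param covariate_sigma_draws posterior draws of sigma from the covariate
#'   model (or its `iam_fit`); both fits must be to the same data.
#' @param functional `"mean"` (default) or `"median"`.
#' @return Proportion of variance explained (at most 1).
#' @export
#' @examples
#' variance_explained(rep(1, 1000), rep(sqrt(0.63), 1000))  # 0.37
variance_explained <- function(null_sigma_draws, covariate_sigma_draws,
                               functional = c("mean", "median")) {
  functional <- match.arg(functional)
  if (inherits(null_sigma_draws, "iam_fit")) {
    null_sigma_draws <- null_sigma_draws$draws[, "sigma"]
  }
  if (inherits(covariate_sigma_draws, "iam_fit")) {
    covariate_sigma_draws <- covariate_sigma_draws$draws[, "sigma"]
  }
  f <- if (functional == "mean") mean else stats::median
  v0 <- f(null_sigma_draws^2)
  v1 <- f(covariate_sigma_draws^2)
  if (!is.finite(v0) || v0 <= 0) stop("null-model variance must be positive")
  1 - v1 / v0
}

#' Leave-one-study-area-out cross-validation
#'
#' Influence of between-area variation on the regression parameters: the
#' model is refitted once per study area with all of that area's sites
#' withheld, and each fold's coefficient summaries are compared with the
#' full-data credible intervals.
#'
#' @param sites an [iam_sites()] object with at least 2 study areas.
#' @param model a [model_config()].
#' @param mcmc an [mcmc_config()]; fold seeds are derived from its seed.
#' @param full_fit optional full-data `iam_fit` to compare against (fitted
#'   here if omitted).
#' @return List with `folds` (per-fold fits), `table` (per-fold coefficient
#'   summaries with `in_full_cri` overlap flags) and `full_fit`.
#' @export
crossvalidate_by_area <- function(sites, model, mcmc, full_fit = NULL) {
  areas <- unique(sites$study_area)
  if (length(areas) < 2) stop("need at least 2 study areas")
  if (any(table(sites$study_area) == sites$n_sites)) {
    stop("one study area contains all sites; nothing to cross-validate")
  }
  if (is.null(full_fit)) full_fit <- fit_iam(sites, model, mcmc)
  full_sum <- posterior_summary(full_fit)
  pars <- grep("^beta_", colnames(full_fit$draws), value = TRUE)
  if (length(pars) == 0) pars <- "mu"
  folds <- list(); rows <- list()
  for (a in areas) {
    keep <- sites$study_area != a
    fmc <- mcmc_config(n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
                       burn_in = mcmc$burn_in, thin = mcmc$thin,
                       seed = mcmc$seed + match(a, areas))
    f <- fit_iam(sites[keep], model, fmc)
    folds[[a]] <- f
    s <- posterior_summary(f, pars)
    s$held_out_area <- a
    s$n_sites <- sum(keep)
    fs <- full_sum[match(pars, full_sum$parameter), ]
    s$in_full_cri <- s$mean >= fs$lower95 & s$mean <= fs$upper95
    rows[[a]] <- s
  }
  list(folds = folds, table = do.call(rbind, c(rows, make.row.names = FALSE)),
       full_fit = full_fit)
}

#' Refit with a single citizen-science source
#'
#' Assesses how each citizen data stream influences the regression
#' parameters by refitting the model with only one citizen source (plus the
#' expert data): a survey-only variant keeping sites with at least one survey
#' replicate, and a report-only variant keeping sites with at least one
#' report. Expert data at retained sites are untouched.
#'
#' @param sites an [iam_sites()] object.
#' @param model a [model_config()].
#' @param mcmc an [mcmc_config()].
#' @return List with `fits` (per variant), `table` (coefficient summaries per
#'   variant, with retained-site counts) and `covariate_ranges` (per-variant
#'   ranges of each model covariate over the retained sites).
#' @export
single_source_refits <- function(sites, model, mcmc) {
  strip <- function(s, drop) {
    keep <- if (drop == "report") lengths(s$survey_counts) > 0
            else lengths(s$report_counts) > 0
    s2 <- s[keep]
    for (i in seq_len(s2$n_sites)) {
      if (drop == "report") s2$report_counts[[i]] <- numeric(0)
      else s2$survey_counts[[i]] <- numeric(0)
    }
    s2
  }
  variants <- list(survey_only = strip(sites, drop = "report"),
                   report_only = strip(sites, drop = "survey"))
  fits <- list(); rows <- list(); ranges <- list()
  for (v in names(variants)) {
    s <- variants[[v]]
    if (s$n_sites < 10) {
      warning("variant ", v, " retains only ", s$n_sites, " sites")
    }
    fits[[v]] <- fit_iam(s, model, mcmc)
    pars <- grep("^beta_", colnames(fits[[v]]$draws), value = TRUE)
    if (length(pars) == 0) pars <- "mu"
    tab <- posterior_summary(fits[[v]], pars)
    tab$variant <- v
    tab$n_sites <- s$n_sites
    rows[[v]] <- tab
    if (length(model$covariates) > 0) {
      ranges[[v]] <- vapply(model$covariates,
                            function(cv) range(s$covariates[[cv]]), numeric(2))
    }
  }
  list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)),
       covariate_ranges = ranges, variants = variants)
}

#' Prior sensitivity of the regression coefficients
#'
#' Refits the model under uniform coefficient priors of different half-widths
#' (default 0.5, 5 and 10) and compares the coefficient posteriors. A
#' posterior piling up against its prior bound (more than 2% of draws within
#' 1% of a bound) is flagged as truncated.
#'
#' @param sites an [iam_sites()] object.
#' @param model a [model_config()]; its `beta_bounds` are replaced by each
#'   width in turn.
#' @param mcmc an [mcmc_config()].
#' @param widths numeric vector of prior half-widths.
#' @return List with `fits` and a `table` of per-width coefficient summaries
#'   with `truncated` flags.
#' @export
prior_sensitivity <- function(sites, model, mcmc, widths = c(0.5, 5, 10)) {
  fits <- list(); rows <- list()
  for (wd in widths) {
    m2 <- model_config(covariates = model$covariates,
                       beta_bounds = c(-wd, wd), m_bounds = model$m_bounds,
                       sigma_bounds = model$sigma_bounds,
                       mu_prior = model$mu_prior,
                       likelihood_mode = model$likelihood_mode)
    f <- fit_iam(sites, m2, mcmc)
    fits[[as.character(wd)]] <- f
    pars <- grep("^beta_", colnames(f$draws), value = TRUE)
    tab <- posterior_summary(f, pars)
    tab$prior_halfwidth <- wd
    tab$truncated <- vapply(pars, function(p) {
      d <- f$draws[, p]
      mean(abs(d) > wd * 0.99) > 0.02
    }, TRUE)
    rows[[as.character(wd)]] <- tab
  }
  list(fits = fits,
       table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Quasi-Poisson GLM screening of covariates
#'
#' Log-link quasi-Poisson regression of site-specific abundance estimates
#' (posterior means from a null-model fit) on candidate covariates, giving a
#' classical significance screen with standard errors scaled by the Pearson
#' dispersion estimate. Significant covariates are candidates for inclusion
#' in the IAM itself.
#'
#' @param abundance numeric vector of per-site abundance estimates (e.g. the
#'   `mean` column of [site_abundance()] on a null fit).
#' @param covariates data.frame of candidate covariates, one row per site.
#' @param alpha two-sided significance threshold (default 0.05).
#' @return data.frame with one row per term: `estimate`, `std_error`,
#'   `t_value`, `p_value`, `significant`; the Pearson `dispersion` is
#'   attached as an attribute.
#' @export
glm_screen <- function(abundance, covariates, alpha = 0.05) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(abundance) == nrow(covariates), all(abundance >= 0))
  dat <- cbind(data.frame(.abund = abundance), covariates)
  fml <- stats::as.formula(paste(".abund ~", paste(names(covariates),
                                                   collapse = " + ")))
  fit <- stats::glm(fml, family = stats::quasipoisson(link = "log"),
                    data = dat)
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    std_error = cf[, 2], t_value = cf[, 3],
                    p_value = cf[, 4],
                    significant = cf[, 4] < alpha, row.names = NULL)
  attr(out, "dispersion") <- summary(fit)$dispersion
  attr(out, "fit") <- fit
  out
}

#' Simulation-based parameter recovery
#'
#' Simulates datasets with the study's structure at known parameter values,
#' refits the model to each, and reports per-parameter accuracy (the
#' proportion of 95% credible intervals capturing the generating value, with
#' a binomial standard error) and bias (mean signed error of the posterior
#' means). Replicates that fail the convergence check are reported in the
#' table, never dropped silently.
#'
#' @param truth a [truth_config()]; its seed anchors the replicate seeds.
#' @param n_reps number of simulated replicates (>= 10).
#' @param model a [model_config()]; defaults to the covariates named in the
#'   truth.
#' @param mcmc an [mcmc_config()]; the reduced preset keeps this at desk
#'   scale.
#' @param parameters which generating parameters to score.
#' @return List with `table` (per-parameter `coverage`, `coverage_se`,
#'   `bias`) and `details` (per-replicate point estimates, intervals and
#'   convergence flags).
#' @export
simulation_recovery <- function(truth, n_reps = 20,
                                model = NULL,
                                mcmc = mcmc_config(preset = "reduced"),
                                parameters = c("mu", "p_survey", "p_report",
                                               "m_survey", "m_report",
                                               if (length(truth$beta) > 0)
                                                 paste0("beta_", names(truth$beta)))) {
  stopifnot(n_reps >= 10)
  if (is.null(model)) model <- model_config(covariates = names(truth$beta))
  true_vals <- c(mu = truth$mu, sigma = truth$sigma, omega = truth$omega,
                 p_survey = truth$p_survey, p_report = truth$p_report,
                 m_survey = truth$m_survey, m_report = truth$m_report)
  if (length(truth$beta) > 0) {
    true_vals <- c(true_vals,
                   stats::setNames(truth$beta, paste0("beta_", names(truth$beta))))
  }
  details <- list()
  for (r in seq_len(n_reps)) {
    cfg <- truth
    cfg$seed <- truth$seed + 1000L * r
    sim <- simulate_sites(cfg)
    fmc <- mcmc_config(n_chains = mcmc$n_chains, n_iter = mcmc$n_iter,
                       burn_in = mcmc$burn_in, thin = mcmc$thin,
                       seed = mcmc$seed + r)
    fit <- suppressWarnings(fit_iam(sim$sites, model, fmc))
    s <- posterior_summary(fit, parameters)
    s$rep <- r
    s$truth <- true_vals[parameters]
    s$covered <- s$truth >= s$lower95 & s$truth <= s$upper95
    s$converged <- isTRUE(fit$converged)
    details[[r]] <- s
  }
  det <- do.call(rbind, c(details, make.row.names = FALSE))
  tab <- do.call(rbind, lapply(parameters, function(p) {
    d <- det[det$parameter == p, ]
    cov <- mean(d$covered)
    data.frame(parameter = p, truth = true_vals[[p]],
               coverage = cov,
               coverage_se = sqrt(cov * (1 - cov) / nrow(d)),
               bias = mean(d$mean - d$truth),
               n_converged = sum(d$converged), n_reps = nrow(d))
  }))
  list(table = tab, details = det)
}
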