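# Brute-force term-by-term joint log density: loops over every observation
# with dpois/dnorm/dbinom. Written independently of the package's vectorized
# sufficient-statistics implementation and kept deliberately naive.
oracle_log_joint <- function(params, sites, model) {
  p <- params
  bb <- model$beta_bounds
  mb <- model$m_bounds
  sb <- model$sigma_bounds
  if (p$sigma <= sb[1] || p$sigma >= sb[2] ||
      p$p_survey <= 0 || p$p_survey >= 1 ||
      p$p_report <= 0 || p$p_report >= 1 ||
      p$omega <= 0 || p$omega >= 1 ||
      p$m_survey <= mb[1] || p$m_survey >= mb[2] ||
      p$m_report <= mb[1] || p$m_report >= mb[2] ||
      any(p$beta <= bb[1]) || any(p$beta >= bb[2]) ||
      !all(p$z %in% c(0, 1))) {
    return(-Inf)
  }
  lp <- dnorm(p$mu, model$mu_prior[1], model$mu_prior[2], log = TRUE)
  for (b in p$beta) lp <- lp + dunif(b, bb[1], bb[2], log = TRUE)
  lp <- lp + dunif(p$sigma, sb[1], sb[2], log = TRUE)
  lp <- lp + dunif(p$m_survey, mb[1], mb[2], log = TRUE)
  lp <- lp + dunif(p$m_report, mb[1], mb[2], log = TRUE)
  X <- if (!is.null(sites$covariates)) {
    as.matrix(sites$covariates[, model$covariates, drop = FALSE])
  } else {
    matrix(0, sites$n_sites, 0)
  }
  enc <- function(v) {
    if (model$likelihood_mode == "round_half_up") floor(v + 0.5) else v
  }
  logpois <- function(x, mean) {
    if (model$likelihood_mode == "round_half_up") {
      dpois(x, mean, log = TRUE)
    } else {
      # Poisson density with the factorial generalised via the gamma function
      if (mean == 0) {
        if (x == 0) 0 else -Inf
      } else {
        x * log(mean) - mean - lgamma(x + 1)
      }
    }
  }
  for (i in seq_len(sites$n_sites)) {
    lin <- p$mu + sum(X[i, ] * p$beta)
    lp <- lp + dnorm(p$log_lambda[i], lin, p$sigma, log = TRUE)
    lp <- lp + dbinom(p$z[i], 1, p$omega, log = TRUE)
    N <- p$z[i] * exp(p$log_lambda[i])
    for (yv in enc(sites$survey_counts[[i]])) {
      lp <- lp + logpois(yv, N * p$p_survey + p$m_survey)
    }
    for (uv in enc(sites$report_counts[[i]])) {
      lp <- lp + logpois(uv, N * p$p_report + p$m_report)
    }
    if (!is.na(sites$expert_count[i])) {
      lp <- lp + dpois(sites$expert_count[i], N, log = TRUE)
    }
  }
  lp
}

# small random site instance with all three data streams, half-integer
# survey encodings included
random_instance <- function(seed, n_sites = 3) {
  set.seed(seed)
  y <- lapply(seq_len(n_sites), function(i) {
    sample(c(0, 1.5, 3.5, 7, 15), sample(1:4, 1), replace = TRUE)
  })
  u <- lapply(seq_len(n_sites), function(i) {
    rpois(sample(1:3, 1), 2)
  })
  has_w <- runif(n_sites) < 0.7
  w <- ifelse(has_w, rpois(n_sites, 2), NA)
  occ <- ifelse(is.na(w), "unknown", ifelse(w > 0, "present", "absent"))
  sites <- iam_sites(
    site_id = paste0("s", seq_len(n_sites)),
    study_area = sample(c("A", "B"), n_sites, replace = TRUE),
    survey_counts = y, report_counts = u,
    expert_count = w, occupancy = occ,
    covariates = data.frame(imd = sample(1:10, n_sites, replace = TRUE),
                            popdens = rnorm(n_sites)))
  z <- ifelse(occ == "present", 1, ifelse(occ == "absent", 0,
                                          rbinom(n_sites, 1, 0.5)))
  params <- list(mu = rnorm(1, 1, 1), beta = runif(2, -0.5, 0.5),
                 sigma = runif(1, 0.3, 2), p_survey = runif(1, 0.05, 0.9),
                 p_report = runif(1, 0.05, 0.9),
                 m_survey = runif(1, 0.1, 4), m_report = runif(1, 0.1, 4),
                 omega = runif(1, 0.1, 0.9),
                 log_lambda = rnorm(n_sites, 0.5, 1), z = z)
  list(sites = sites, params = params)
}

# small fitted-scale dataset shared by several MCMC tests
small_sim <- function(seed = 42, n_sites = 60) {
  simulate_sites(truth_config(n_sites = n_sites, n_study_areas = 3,
                              seed = seed))
}

short_mcmc <- function(seed = 1, n_chains = 3) {
  mcmc_config(n_chains = n_chains, n_iter = 1500, burn_in = 500, seed = seed)
}
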