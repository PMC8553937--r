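#' Generating truth for synthetic multi-site cat count data
#'
#' Collects the parameters that define a simulated study: the log-abundance
#' regression, the zero-inflation (occupancy) probability, the two citizen
#' observation processes (detection probability and expected
#' misidentifications per replicate), expert coverage, and replicate effort.
#'
#' Defaults emulate the study design the model was developed for: 162 sites
#' across 5 urban areas, expert coverage 104/162 sites, detection
#' probabilities 0.245 (reports) and 0.179 (surveys), misidentification means
#' 1.8 and 0.72, covariate effects -0.32 (IMD decile, unstandardized 1-10)
#' and 0.31 (standardized population density). The intercept (2.4) and
#' residual SD (1.26) are calibrated so that the median occupied-site
#' intensity is about 1.9 cats (9.3 cats per km2 on a 0.2 km2 site) and the
#' covariates explain about 37% of the log-abundance variance.
#'
#' @param n_sites number of sites.
#' @param n_study_areas number of study areas (sites are split evenly).
#' @param mu log-abundance intercept.
#' @param beta named numeric vector of covariate effects; covariates named
#'   `imd` (integer deciles 1-10) and `popdens` (standardized) are simulated
#'   by default.
#' @param sigma residual site SD on the log scale, in (0, 3).
#' @param omega occupancy probability in (0, 1).
#' @param p_survey,p_report per-replicate detection probabilities in (0, 1).
#' @param m_survey,m_report expected misidentified (owned) cats per replicate,
#'   in \[0, 5).
#' @param expert_coverage fraction of sites with expert data.
#' @param survey_reps,report_reps integer ranges (length-2) for the number of
#'   replicates per site.
#' @param covariate_correlation correlation injected between IMD and density
#'   (0 = independent; real areas confound them).
#' @param seed integer seed.
#' @return A validated list of class `truth_config`.
#' @export
truth_config <- function(n_sites = 162, n_study_areas = 5,
                         mu = 2.4, beta = c(imd = -0.32, popdens = 0.31),
                         sigma = 1.26, omega = 0.8,
                         p_survey = 0.179, p_report = 0.245,
                         m_survey = 0.72, m_report = 1.8,
                         expert_coverage = 104 / 162,
                         survey_reps = c(5, 30), report_reps = c(1, 10),
                         covariate_correlation = 0, seed = 1) {
  stopifnot(n_sites >= 1, n_study_areas >= 1, n_study_areas <= n_sites)
  for (p in c(p_survey, p_report, omega)) {
    if (!is.finite(p) || p <= 0 || p > 1) {
      stop("probabilities (p_survey, p_report, omega) must lie in (0,1]")
    }
  }
  if (sigma < 0 || sigma >= 3) stop("sigma must lie in [0, 3)")
  if (m_survey < 0 || m_survey >= 5 || m_report < 0 || m_report >= 5) {
    stop("misidentification means must lie in [0, 5)")
  }
  if (expert_coverage < 0 || expert_coverage > 1) {
    stop("expert_coverage must lie in [0, 1]")
  }
  if (is.null(names(beta)) && length(beta) > 0) {
    names(beta) <- if (length(beta) == 2) c("imd", "popdens")
                   else paste0("x", seq_along(beta))
  }
  stopifnot(length(survey_reps) == 2, length(report_reps) == 2,
            all(survey_reps >= 1), all(report_reps >= 0),
            survey_reps[1] <= survey_reps[2], report_reps[1] <= report_reps[2])
  structure(list(n_sites = as.integer(n_sites),
                 n_study_areas = as.integer(n_study_areas),
                 mu = mu, beta = beta, sigma = sigma, omega = omega,
                 p_survey = p_survey, p_report = p_report,
                 m_survey = m_survey, m_report = m_report,
                 expert_coverage = expert_coverage,
                 survey_reps = as.integer(survey_reps),
                 report_reps = as.integer(report_reps),
                 covariate_correlation = covariate_correlation,
                 seed = as.integer(seed)),
            class = "truth_config")
}

## independent sub-seeds per data stream, so e.g. changing replicate effort
## never perturbs the latent states; kept < 2^31
stream_seed <- function(seed, stream) {
  offs <- c(latent = 1L, survey = 2L, report = 3L, expert = 4L, points = 5L)
  (abs(as.integer(seed)) %% 199999991L) * 10L + offs[[stream]]
}

#' Simulate a replicated multi-site unowned-cat dataset
#'
#' Draws site covariates, latent log intensities
#' `log(lambda_i) = mu + sum_j beta_j x_ji + eps_i` with
#' `eps_i ~ N(0, sigma^2)`, occupancy `z_i ~ Bernoulli(omega)`, and realized
#' abundance `N_i = z_i * lambda_i`. Replicate survey counts are
#' `Poisson(N_i p_survey + m_survey)`, report counts
#' `Poisson(N_i p_report + m_report)`, and at a fraction `expert_coverage` of
#' sites an expert count `w_i ~ Poisson(N_i)` is recorded together with an
#' occupancy flag. The expert protocol is treated as accurate at the level of
#' presence or absence, so the flag carries the true occupancy state at
#' surveyed sites ("present"/"absent"); the count itself remains a Poisson
#' draw, so an occupied low-abundance site can record `w_i = 0` while staying
#' flagged present. Random streams are split per data type, and the whole
#' draw is reproducible for a fixed seed.
#'
#' @param config a [truth_config()].
#' @param covariate_table optional data.frame of user-supplied site
#'   covariates (one row per site) overriding the simulated ones; must have
#'   `length(config$beta)` numeric columns.
#' @param points if `TRUE`, also emit the raw geo-referenced sighting records
#'   (`sightings` data.frame in the [read_sightings()] schema) with sites laid
#'   out more than 500 m apart and records jittered within each site, so the
#'   clustering stage can be exercised on the same draw.
#' @return List of class `iam_simulation` with `sites` (an [iam_sites()]
#'   object), `truth` (the config plus realized `lambda`, `z`, `N`, `eps` and
#'   the covariate matrix), and optionally `sightings`.
#' @export
#' @examples
#' sim <- simulate_sites(truth_config(n_sites = 20, seed = 7))
#' sim$sites
simulate_sites <- function(config, covariate_table = NULL, points = FALSE) {
  stopifnot(inherits(config, "truth_config"))
  n <- config$n_sites
  k <- length(config$beta)

  set.seed(stream_seed(config$seed, "latent"))
  if (!is.null(covariate_table)) {
    X <- as.matrix(as.data.frame(covariate_table))
    stopifnot(nrow(X) == n, ncol(X) == k)
    colnames(X) <- names(config$beta)
  } else if (k > 0) {
    X <- matrix(0, n, k, dimnames = list(NULL, names(config$beta)))
    if ("imd" %in% colnames(X)) X[, "imd"] <- sample(1:10, n, replace = TRUE)
    z01 <- stats::rnorm(n)
    for (nm in setdiff(colnames(X), "imd")) {
      e <- stats::rnorm(n)
      if (config$covariate_correlation != 0 && "imd" %in% colnames(X)) {
        r <- config$covariate_correlation
        imd_std <- (X[, "imd"] - mean(X[, "imd"])) /
          stats::sd(X[, "imd"])
        X[, nm] <- r * imd_std + sqrt(1 - r^2) * e
      } else {
        X[, nm] <- e
      }
    }
  } else {
    X <- matrix(0, n, 0)
  }
  eps <- stats::rnorm(n, 0, config$sigma)
  eta <- config$mu + as.vector(X %*% config$beta) + eps
  if (any(abs(eta) > 50)) {
    stop("non-finite linear predictor (|log lambda| > 50) at site(s): ",
         paste(which(abs(eta) > 50), collapse = ", "))
  }
  lambda <- exp(eta)
  z <- stats::rbinom(n, 1, config$omega)
  N <- z * lambda
  n_expert <- round(config$expert_coverage * n)
  expert_sites <- sort(sample.int(n, n_expert))
  study_area <- paste0("area_", rep_len(seq_len(config$n_study_areas), n))

  set.seed(stream_seed(config$seed, "survey"))
  n_y <- sample(config$survey_reps[1]:config$survey_reps[2], n, replace = TRUE)
  y <- lapply(seq_len(n), function(i) {
    stats::rpois(n_y[i], N[i] * config$p_survey + config$m_survey)
  })
  set.seed(stream_seed(config$seed, "report"))
  n_u <- sample(config$report_reps[1]:config$report_reps[2], n, replace = TRUE)
  u <- lapply(seq_len(n), function(i) {
    stats::rpois(n_u[i], N[i] * config$p_report + config$m_report)
  })
  set.seed(stream_seed(config$seed, "expert"))
  w <- rep(NA_real_, n)
  w[expert_sites] <- stats::rpois(n_expert, N[expert_sites])
  ## the expert protocol is accurate at the level of presence or absence, so
  ## the occupancy flag carries the true occupancy state at surveyed sites
  ## (a count of 0 at an occupied site stays "present": the count is a
  ## Poisson draw, the presence confirmation is not)
  occ <- rep("unknown", n)
  occ[expert_sites] <- ifelse(z[expert_sites] == 1, "present", "absent")

  site_id <- sprintf("site_%03d", seq_len(n))
  sites <- iam_sites(site_id = site_id, study_area = study_area,
                     survey_counts = y, report_counts = u,
                     expert_count = w, occupancy = occ,
                     covariates = if (k > 0) as.data.frame(X))
  out <- list(sites = sites,
              truth = c(unclass(config),
                        list(lambda = lambda, z = z, N = N, eps = eps, X = X,
                             expert_sites = expert_sites)))
  if (points) out$sightings <- sightings_from_sites(sites, config$seed)
  structure(out, class = "iam_simulation")
}

## raw-point form: site centres on a sparse grid (>= 1500 m apart), records
## jittered within +/-100 m so each site is one 500-m single-linkage cluster
sightings_from_sites <- function(sites, seed) {
  set.seed(stream_seed(seed, "points"))
  n <- sites$n_sites
  g <- ceiling(sqrt(n))
  cx <- ((seq_len(n) - 1) %% g) * 2000
  cy <- ((seq_len(n) - 1) %/% g) * 2000
  rows <- list()
  rid <- 0
  for (i in seq_len(n)) {
    vals <- c(sites$survey_counts[[i]], sites$report_counts[[i]],
              if (!is.na(sites$expert_count[i])) sites$expert_count[i])
    types <- c(rep("survey", length(sites$survey_counts[[i]])),
               rep("report", length(sites$report_counts[[i]])),
               if (!is.na(sites$expert_count[i])) "expert")
    m <- length(vals)
    rows[[i]] <- data.frame(
      record_id = sprintf("r%05d", rid + seq_len(m)),
      observer_type = types,
      x = cx[i] + stats::runif(m, -100, 100),
      y = cy[i] + stats::runif(m, -100, 100),
      crs = "metres",
      raw_value = vals,
      study_area = sites$study_area[i])
    rid <- rid + m
  }
  out <- do.call(rbind, rows)
  ## true generating site per record, for covariate lookup after clustering
  attr(out, "site_index") <- rep(seq_len(n), vapply(rows, nrow, 0L))
  out
}

#' Generate a synthetic small-area statistics table
#'
#' Stand-in for the national small-area census geographies (LSOAs, SOAs and
#' data zones) used when projecting abundance: each area carries a country, a
#' deprivation measure (decile 1-10 or UK-consistent adjusted quintile 1-5),
#' a human population density and a land area. Land areas can be rescaled so
#' each country's total land matches a given figure exactly, which keeps
#' national bookkeeping exact.
#'
#' @param n_areas total number of areas, or a named integer vector of counts
#'   per country.
#' @param country_mix named proportions per country (ignored when `n_areas`
#'   is named). Default is a UK-shaped mix.
#' @param seed integer seed.
#' @param mean_density target mean population density (people per km2);
#'   densities are lognormal.
#' @param density_sdlog lognormal SD of density on the log scale.
#' @param mean_land_area mean land area per area unit (km2).
#' @param land_totals optional named vector of exact per-country land totals
#'   (km2) to rescale to.
#' @param imd_scale `"decile"` (1-10) or `"quintile"` (1-5).
#' @return data.frame with columns `area_id`, `country`, `imd_decile` or
#'   `imd_quintile`, `pop_density`, `land_area`, `urban`.
#' @export
#' @examples
#' areas <- make_area_table(100, seed = 1)
#' range(areas$imd_decile)
make_area_table <- function(n_areas,
                            country_mix = c(England = 0.8017,
                                            Wales = 0.0383,
                                            Scotland = 0.1444,
                                            `N. Ireland` = 0.0156),
                            seed = 1, mean_density = 5303,
                            density_sdlog = 0.9, mean_land_area = 0.904,
                            land_totals = NULL, imd_scale = c("decile", "quintile")) {
  imd_scale <- match.arg(imd_scale)
  set.seed(abs(as.integer(seed)) %% 2000000011L)
  if (!is.null(names(n_areas))) {
    counts <- as.integer(n_areas)
    names(counts) <- names(n_areas)
  } else {
    stopifnot(n_areas >= 1)
    counts <- round(n_areas * country_mix / sum(country_mix))
    counts[1] <- counts[1] + (n_areas - sum(counts))
  }
  country <- rep(names(counts), counts)
  n <- length(country)
  imd <- if (imd_scale == "decile") sample(1:10, n, replace = TRUE)
         else sample(1:5, n, replace = TRUE)
  meanlog <- log(mean_density) - density_sdlog^2 / 2
  dens <- stats::rlnorm(n, meanlog, density_sdlog)
  land <- stats::rlnorm(n, log(mean_land_area) - 0.5^2 / 2, 0.5)
  if (!is.null(land_totals)) {
    for (cn in names(land_totals)) {
      idx <- country == cn
      land[idx] <- land[idx] * land_totals[[cn]] / sum(land[idx])
    }
  }
  out <- data.frame(area_id = sprintf("A%06d", seq_len(n)), country = country,
                    imd = imd, pop_density = dens, land_area = land,
                    urban = TRUE)
  names(out)[names(out) == "imd"] <- paste0("imd_", imd_scale)
  out
}

#' Per-country bookkeeping of an area table
#'
#' @param areas data.frame as produced by [make_area_table()] or
#'   [read_areas()].
#' @return data.frame with one row per country plus a `Total` row, giving
#'   `n_areas` and summed `land_km2`.
#' @export
area_summary <- function(areas) {
  stopifnot(all(c("country", "land_area") %in% names(areas)))
  tab <- stats::aggregate(list(land_km2 = areas$land_area),
                          by = list(country = areas$country), FUN = sum)
  tab$n_areas <- as.vector(table(areas$country)[tab$country])
  tab <- tab[, c("country", "n_areas", "land_km2")]
  rbind(tab, data.frame(country = "Total", n_areas = sum(tab$n_areas),
                        land_km2 = sum(tab$land_km2)))
}
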