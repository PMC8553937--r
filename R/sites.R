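#' Site-structured count data for the integrated abundance model
#'
#' Builds the container holding, for each site, the replicate citizen-science
#' counts, the optional expert consensus count, the expert occupancy status,
#' the site covariates, and the study-area label. This is the object
#' [fit_iam()] consumes.
#'
#' @param site_id character or integer vector of unique site identifiers.
#' @param study_area character vector of study-area labels, one per site.
#' @param survey_counts list of numeric vectors; replicate door-to-door survey
#'   counts per site (encoded midpoints, so values such as 1.5 are legal).
#' @param report_counts list of numeric vectors; replicate resident-report
#'   counts per site (non-negative integers).
#' @param expert_count numeric vector, one per site; the expert consensus
#'   count, or `NA` where no expert data exist.
#' @param occupancy character vector in `c("present", "absent", "unknown")`;
#'   expert-inferred occupancy status per site.
#' @param covariates optional data.frame of site covariates (one row per
#'   site); column names are the covariate names used in [model_config()].
#'
#' @return An object of class `iam_sites`: a list with the validated fields
#'   above and `n_sites`.
#' @export
#' @examples
#' s <- iam_sites(
#'   site_id = c("a", "b"), study_area = c("A1", "A1"),
#'   survey_counts = list(c(1.5, 0), 3.5),
#'   report_counts = list(2, numeric(0)),
#'   expert_count = c(4, NA), occupancy = c("present", "unknown"),
#'   covariates = data.frame(imd = c(3, 8), popdens = c(0.2, -1))
#' )
#' s$n_sites
iam_sites <- function(site_id, study_area, survey_counts, report_counts,
                      expert_count = NULL, occupancy = NULL,
                      covariates = NULL) {
  n <- length(site_id)
  if (anyDuplicated(site_id)) stop("site_id values must be unique")
  if (length(study_area) == 1) study_area <- rep(study_area, n)
  if (length(study_area) != n) stop("study_area must have one label per site")
  if (!is.list(survey_counts)) survey_counts <- as.list(survey_counts)
  if (!is.list(report_counts)) report_counts <- as.list(report_counts)
  if (length(survey_counts) != n || length(report_counts) != n) {
    stop("survey_counts and report_counts must have one element per site")
  }
  survey_counts <- lapply(survey_counts, as.numeric)
  report_counts <- lapply(report_counts, as.numeric)
  bad <- vapply(survey_counts, function(v) any(!is.finite(v) | v < 0), TRUE) |
    vapply(report_counts, function(v) any(!is.finite(v) | v < 0), TRUE)
  if (any(bad)) {
    stop("negative or non-finite counts at site(s): ",
         paste(site_id[bad], collapse = ", "))
  }
  n_cit <- lengths(survey_counts) + lengths(report_counts)
  if (any(n_cit == 0)) {
    stop("site(s) without any citizen replicate: ",
         paste(site_id[n_cit == 0], collapse = ", "))
  }
  if (is.null(expert_count)) expert_count <- rep(NA_real_, n)
  expert_count <- as.numeric(expert_count)
  if (length(expert_count) != n) stop("expert_count must have one value per site")
  if (any(expert_count < 0, na.rm = TRUE)) stop("expert counts must be >= 0")
  if (is.null(occupancy)) {
    occupancy <- ifelse(is.na(expert_count), "unknown",
                        ifelse(expert_count > 0, "present", "absent"))
  }
  occupancy <- as.character(occupancy)
  if (!all(occupancy %in% c("present", "absent", "unknown"))) {
    stop("occupancy must be one of 'present', 'absent', 'unknown'")
  }
  inc <- !is.na(expert_count) & expert_count > 0 & occupancy != "present"
  if (any(inc)) {
    stop("expert count > 0 but occupancy not 'present' at site(s): ",
         paste(site_id[inc], collapse = ", "))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per site")
    if (any(!vapply(covariates, is.numeric, TRUE))) {
      stop("all covariates must be numeric")
    }
    if (anyNA(covariates)) stop("covariates must not contain NA")
  }
  structure(
    list(site_id = as.character(site_id), study_area = as.character(study_area),
         survey_counts = survey_counts, report_counts = report_counts,
         expert_count = expert_count, occupancy = occupancy,
         covariates = covariates, n_sites = n),
    class = "iam_sites"
  )
}

#' @export
print.iam_sites <- function(x, ...) {
  cat("<iam_sites> ", x$n_sites, " sites in ",
      length(unique(x$study_area)), " study area(s)\n", sep = "")
  cat("  survey replicates: ", sum(lengths(x$survey_counts)),
      "; report replicates: ", sum(lengths(x$report_counts)), "\n", sep = "")
  ne <- sum(!is.na(x$expert_count))
  cat("  expert data at ", ne, "/", x$n_sites, " sites (",
      round(100 * ne / x$n_sites, 1), "%)\n", sep = "")
  if (!is.null(x$covariates)) {
    cat("  covariates: ", paste(names(x$covariates), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Subset an iam_sites object
#'
#' @param x an `iam_sites` object.
#' @param i logical or integer index over sites.
#' @param ... unused.
#' @return An `iam_sites` object containing the selected sites.
#' @export
`[.iam_sites` <- function(x, i, ...) {
  iam_sites(site_id = x$site_id[i], study_area = x$study_area[i],
            survey_counts = x$survey_counts[i],
            report_counts = x$report_counts[i],
            expert_count = x$expert_count[i], occupancy = x$occupancy[i],
            covariates = if (!is.null(x$covariates)) x$covariates[i, , drop = FALSE])
}

#' Fraction of sites with expert data
#'
#' Expert (community-team) coverage of the site network, as a percentage.
#' Expert data at a subset of sites is what lets the model identify citizen
#' detection and misidentification rates.
#'
#' @param sites an `iam_sites` object.
#' @return Percentage of sites carrying an expert consensus count.
#' @export
expert_coverage_percent <- function(sites) {
  stopifnot(inherits(sites, "iam_sites"))
  100 * sum(!is.na(sites$expert_count)) / sites$n_sites
}
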