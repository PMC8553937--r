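#' Encode a survey multiple-choice response as a count
#'
#' The door-to-door survey records local unowned-cat numbers as one of the
#' categories none / 1-2 / 3-4 / 5-9 / 10 or more. Ranges are encoded by
#' their central value; the open top category is encoded as 15.
#'
#' @param choice character vector of survey categories. Both ASCII hyphens and
#'   en-dashes are accepted; "10+" is a synonym for "10 or more".
#' @return Numeric vector of encoded counts.
#' @export
#' @examples
#' encode_survey_response(c("none", "1-2", "3-4", "5-9", "10 or more"))
encode_survey_response <- function(choice) {
  key <- gsub("–", "-", trimws(tolower(as.character(choice))))
  map <- c("none" = 0, "0" = 0, "1-2" = 1.5, "3-4" = 3.5, "5-9" = 7,
           "10 or more" = 15, "10+" = 15)
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(as.character(choice)[is.na(out)])
    stop("unrecognized survey category: ", paste(sQuote(bad), collapse = ", "))
  }
  out
}

#' Diameter of a circular home range
#'
#' Utility linking an assumed maximum home-range area to the clustering
#' radius: a 20 ha circular home range has a diameter of just over 504 m,
#' which motivates the default 500 m clustering radius.
#'
#' @param area_ha home-range area in hectares.
#' @return Diameter in metres of a circle with that area.
#' @export
#' @examples
#' floor(home_range_diameter_m(20))  # 504
home_range_diameter_m <- function(area_ha) {
  stopifnot(is.numeric(area_ha), all(area_ha > 0))
  2 * sqrt(area_ha * 1e4 / pi)
}

## pairwise distances in metres, honouring the declared CRS
sighting_distances <- function(x, y, crs) {
  crs <- unique(crs)
  if (length(crs) > 1) {
    stop("mixed coordinate systems (", paste(crs, collapse = ", "),
         "); convert to a single CRS before clustering")
  }
  if (!crs %in% c("metres", "wgs84")) {
    stop("unknown crs ", sQuote(crs), "; expected 'metres' or 'wgs84'")
  }
  if (crs == "metres") {
    as.matrix(stats::dist(cbind(x, y)))
  } else {
    message("lon/lat coordinates: using haversine distances")
    geosphere::distm(cbind(x, y), fun = geosphere::distHaversine)
  }
}

#' Cluster geo-referenced sightings into sites
#'
#' Partitions sighting records into sites by single-linkage clustering at a
#' fixed radius: any two records within `radius_m` of each other share a site,
#' and membership chains transitively, so a site is a connected component of
#' the proximity graph. Individual records are kept as replicate counts within
#' each site. Implemented as union-find over all pairs at or below the radius;
#' the assignment is invariant to record order and to rigid translation of the
#' coordinates.
#'
#' @param records data.frame with numeric columns `x`, `y` and a `crs` column
#'   (`"metres"` for planar metre coordinates, `"wgs84"` for lon/lat, in which
#'   case haversine distances are used).
#' @param radius_m linkage radius in metres (default 500, from an assumed
#'   20 ha maximum home range, see [home_range_diameter_m()]).
#' @return Integer vector of site labels, one per record. Labels are assigned
#'   in order of each cluster's first member after a lexicographic sort on
#'   (x, y), so they do not depend on the input row order.
#' @export
#' @examples
#' r <- data.frame(x = c(0, 400, 800), y = 0, crs = "metres")
#' cluster_sightings(r, radius_m = 500)  # one chained site
cluster_sightings <- function(records, radius_m = 500) {
  stopifnot(is.data.frame(records), all(c("x", "y") %in% names(records)))
  if (!is.numeric(records$x) || !is.numeric(records$y) ||
      any(!is.finite(records$x)) || any(!is.finite(records$y))) {
    stop("all records must carry finite numeric coordinates")
  }
  if (!is.numeric(radius_m) || length(radius_m) != 1 || radius_m < 0) {
    stop("radius_m must be a single non-negative number")
  }
  crs <- if ("crs" %in% names(records)) records$crs else "metres"
  n <- nrow(records)
  if (n == 0) return(integer(0))
  d <- sighting_distances(records$x, records$y, crs)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(upper.tri(d) & d <= radius_m, arr.ind = TRUE)
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))

  ## deterministic labels: order of first appearance after (x, y) sort
  ord <- order(records$x, records$y)
  first <- ord[!duplicated(root[ord])]
  labels <- stats::setNames(seq_along(first), root[first])
  unname(labels[as.character(root)])
}

#' Assemble site-structured data from assigned sighting records
#'
#' Reduces clustered sighting records to one [iam_sites()] row per site:
#' survey responses become encoded replicate counts, reports become replicate
#' counts, and expert records are reduced to one consensus count per site (the
#' sum over expert records, which count distinct individuals with no double
#' counting). Expert occupancy is `"present"` if any expert count is positive,
#' `"absent"` if experts surveyed the site and found none, `"unknown"` where
#' no expert visited. Sites with no citizen replicate at all are dropped with
#' a warning, since the model needs at least one citizen observation per site.
#'
#' @param records data.frame with columns `observer_type`
#'   (`survey`/`report`/`expert`), `raw_value` (a survey category for surveys,
#'   a non-negative count otherwise) and `study_area`.
#' @param assignments integer vector of site labels, e.g. from
#'   [cluster_sightings()].
#' @param covariate_table optional data.frame of site covariates, keyed by a
#'   `site_id` column (matching the assignment labels) or by `study_area`.
#'   All non-key numeric columns become model covariates.
#' @return An `iam_sites` object.
#' @export
build_site_data <- function(records, assignments, covariate_table = NULL) {
  stopifnot(is.data.frame(records),
            all(c("observer_type", "raw_value", "study_area") %in% names(records)))
  if (length(assignments) != nrow(records) || anyNA(assignments)) {
    stop("every record must carry a site assignment")
  }
  if (!all(records$observer_type %in% c("survey", "report", "expert"))) {
    stop("observer_type must be 'survey', 'report' or 'expert'")
  }
  ids <- sort(unique(assignments))
  enc <- function(r) {
    if (r$observer_type[1] == "survey" && !is.numeric(records$raw_value)) {
      encode_survey_response(r$raw_value)
    } else {
      as.numeric(r$raw_value)
    }
  }
  y <- u <- vector("list", length(ids))
  w <- rep(NA_real_, length(ids))
  occ <- rep("unknown", length(ids))
  area <- character(length(ids))
  for (k in seq_along(ids)) {
    r <- records[assignments == ids[k], , drop = FALSE]
    sv <- r[r$observer_type == "survey", , drop = FALSE]
    rp <- r[r$observer_type == "report", , drop = FALSE]
    ex <- r[r$observer_type == "expert", , drop = FALSE]
    y[[k]] <- if (nrow(sv)) enc(sv) else numeric(0)
    u[[k]] <- if (nrow(rp)) as.numeric(rp$raw_value) else numeric(0)
    if (nrow(ex)) {
      w[k] <- sum(as.numeric(ex$raw_value))
      occ[k] <- if (w[k] > 0) "present" else "absent"
    }
    area[k] <- as.character(r$study_area[1])
  }
  keep <- lengths(y) + lengths(u) > 0
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " site(s) with no citizen replicates: ",
            paste(ids[!keep], collapse = ", "))
  }
  covariates <- NULL
  if (!is.null(covariate_table)) {
    covariate_table <- as.data.frame(covariate_table)
    if ("site_id" %in% names(covariate_table)) {
      m <- match(as.character(ids[keep]), as.character(covariate_table$site_id))
      key <- "site_id"
    } else if ("study_area" %in% names(covariate_table)) {
      m <- match(area[keep], as.character(covariate_table$study_area))
      key <- "study_area"
    } else {
      stop("covariate_table needs a 'site_id' or 'study_area' key column")
    }
    if (anyNA(m)) stop("covariate_table does not cover every site")
    covariates <- covariate_table[m, setdiff(names(covariate_table), key),
                                  drop = FALSE]
    rownames(covariates) <- NULL
  }
  iam_sites(site_id = ids[keep], study_area = area[keep],
            survey_counts = y[keep], report_counts = u[keep],
            expert_count = w[keep], occupancy = occ[keep],
            covariates = covariates)
}

#' Standardize a covariate, keeping the transform
#'
#' Centres and scales a covariate to mean 0 and SD 1 using the population
#' (n-divisor) SD, and returns the transform so that new areas can later be
#' standardized against the *fitting* data's mean and SD rather than their
#' own.
#'
#' @param values numeric vector with at least two distinct values.
#' @return List with `values` (standardized), `center` (mean) and `scale`
#'   (population SD), of class `cov_scaler`.
#' @seealso [apply_scaler()], [invert_scaler()]
#' @export
#' @examples
#' standardize_covariate(c(1, 3))$values  # -1, 1
standardize_covariate <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || !all(is.finite(values))) {
    stop("need at least two finite values")
  }
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) stop("covariate has zero variance; cannot standardize")
  structure(list(values = (values - m) / s, center = m, scale = s),
            class = "cov_scaler")
}

#' Apply a stored standardization to new values
#' @param values numeric vector on the raw scale.
#' @param scaler a `cov_scaler` from [standardize_covariate()].
#' @return Standardized values.
#' @export
apply_scaler <- function(values, scaler) {
  stopifnot(inherits(scaler, "cov_scaler"))
  (as.numeric(values) - scaler$center) / scaler$scale
}

#' Invert a stored standardization
#' @param std numeric vector on the standardized scale.
#' @param scaler a `cov_scaler` from [standardize_covariate()].
#' @return Values on the original scale.
#' @export
invert_scaler <- function(std, scaler) {
  stopifnot(inherits(scaler, "cov_scaler"))
  as.numeric(std) * scaler$scale + scaler$center
}
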