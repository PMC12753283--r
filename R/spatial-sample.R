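# Observation container shared by every fitting module.

#' Apply right censoring at a threshold
#'
#' Values below the threshold pass through as events (`delta = 1`); values at
#' or above it are replaced by the threshold and flagged censored
#' (`delta = 0`). Ties with the threshold are censored. The transformation is
#' idempotent.
#'
#' @param response Positive raw responses.
#' @param threshold Positive censoring point \eqn{y^*}.
#' @return A tibble with columns `response` (raw), `censored_response` and
#'   `delta` (1 event / 0 censored).
#' @examples
#' apply_censoring(c(3.4, 6, 7), threshold = 6)
#' @export
apply_censoring <- function(response, threshold) {
  if (any(!is.finite(response)) || any(response <= 0)) {
    stop_validation("`response` must be positive and finite.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_validation("`threshold` must be a single positive number.")
  }
  tibble::tibble(
    response = response,
    censored_response = pmin(response, threshold),
    delta = as.numeric(response < threshold)
  )
}

#' Assemble a spatial sample for censored Weibull regression
#'
#' Builds the observation container used by all fitting functions from a
#' site-level data frame: one row per site with an id, two planar
#' coordinates, a positive response, and covariates. Censoring at `threshold`
#' is applied to the response; the design matrix carries a leading intercept
#' column.
#'
#' Coordinates are treated as planar and distances as Euclidean, so bandwidth
#' units are whatever the coordinate units are. If the coordinates are
#' geographic degrees this is an approximation the caller accepts.
#'
#' @param data Data frame with one row per observation.
#' @param site_id,coords,response Column names of the site label, the two
#'   coordinates, and the response.
#' @param covariates Character vector of covariate column names; defaults to
#'   every remaining numeric column.
#' @param threshold Censoring point \eqn{y^*} (default 6, a dissolved-oxygen
#'   quality cutoff in ppm).
#' @return A `spatial_sample` object: list with tibble `data` (site_id, u, v,
#'   response, censored_response, delta, covariates), `coords` matrix,
#'   `design` matrix (leading ones column), `covariate_names`, `threshold`.
#' @examples
#' df <- tibble::tibble(site_id = c("a", "b", "c", "d", "e"),
#'                      u = 1:5, v = 5:1,
#'                      y = c(3.4, 5.8, 6.7, 4.2, 5.1), x1 = rnorm(5))
#' spatial_sample(df, response = "y", threshold = 6)
#' @export
spatial_sample <- function(data, site_id = "site_id", coords = c("u", "v"),
                           response = "y", covariates = NULL, threshold = 6) {
  data <- tibble::as_tibble(data)
  needed <- c(site_id, coords, response)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("missing required column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  if (is.null(covariates)) {
    rest <- setdiff(names(data), needed)
    covariates <- rest[vapply(data[rest], is.numeric, logical(1))]
  }
  cens <- apply_censoring(data[[response]], threshold)
  out <- tibble::tibble(
    site_id = as.character(data[[site_id]]),
    u = as.numeric(data[[coords[1]]]),
    v = as.numeric(data[[coords[2]]]),
    response = cens$response,
    censored_response = cens$censored_response,
    delta = cens$delta
  )
  out <- dplyr::bind_cols(out, data[covariates])
  X <- cbind(`(Intercept)` = rep(1, nrow(data)),
             as.matrix(data[covariates]))
  structure(
    list(
      data = out,
      coords = cbind(u = out$u, v = out$v),
      design = X,
      covariate_names = covariates,
      threshold = threshold
    ),
    class = "spatial_sample"
  )
}

#' @export
print.spatial_sample <- function(x, ...) {
  cs <- censoring_summary(x)
  cat(sprintf(
    "Spatial sample: %d sites, %d covariate(s), threshold %g (%d events, %.1f%%)\n",
    cs$n, length(x$covariate_names), x$threshold, cs$events,
    100 * cs$event_fraction))
  print(x$data, ...)
  invisible(x)
}

#' Censoring summary of a spatial sample
#'
#' @param sample A [spatial_sample()] object.
#' @return One-row tibble with `n`, `events` (number of uncensored
#'   observations) and `event_fraction`.
#' @export
censoring_summary <- function(sample) {
  d <- sample$data$delta
  tibble::tibble(n = length(d), events = sum(d == 1),
                 event_fraction = mean(d == 1))
}

#' Validate a spatial sample
#'
#' Checks the container invariants and returns the violations found (an empty
#' tibble when the sample is well formed) rather than raising, so the caller
#' decides how to react. Duplicate coordinates are reported as informational
#' only: zero distances give legal unit kernel weights.
#'
#' @param sample A [spatial_sample()] object.
#' @return Tibble with columns `severity` ("error" or "info") and `message`.
#' @export
validate_sample <- function(sample) {
  v <- list()
  add <- function(severity, message) {
    v[[length(v) + 1]] <<- tibble::tibble(severity = severity, message = message)
  }
  d <- sample$data
  p <- length(sample$covariate_names)
  if (any(!is.finite(d$response)) || any(d$response <= 0)) {
    add("error", "nonpositive response")
  }
  if (any(!is.finite(sample$coords))) add("error", "non-finite coordinates")
  if (anyNA(d)) add("error", "missing values")
  if (nrow(d) < p + 2) add("error", "insufficient observations (need n >= p + 2)")
  cens_ok <- all((d$delta == 0) == (d$censored_response == sample$threshold)) &&
    all(d$censored_response[d$delta == 1] == d$response[d$delta == 1]) &&
    all(d$censored_response[d$delta == 1] < sample$threshold)
  if (!cens_ok) add("error", "censoring bookkeeping inconsistent with threshold")
  if (anyDuplicated(sample$coords) > 0) {
    add("info", "duplicate coordinates (zero distances allowed)")
  }
  if (length(v) == 0) {
    tibble::tibble(severity = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Read / write the site-table CSV schema
#'
#' The delimited schema is: header row, then columns `site_id`, `u`, `v`,
#' `y`, followed by one column per covariate; UTF-8, decimal point.
#'
#' @param path File path.
#' @param threshold Censoring point passed to [spatial_sample()].
#' @return `read_sites_csv()` returns a [spatial_sample()];
#'   `write_sites_csv()` returns `path` invisibly.
#' @export
read_sites_csv <- function(path, threshold = 6) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("site_id", "u", "v", "y")
  if (!all(needed %in% names(df))) {
    stop_validation("input CSV must have columns site_id, u, v, y, <covariates>")
  }
  spatial_sample(df, site_id = "site_id", coords = c("u", "v"),
                 response = "y", threshold = threshold)
}

#' @rdname read_sites_csv
#' @param sample A [spatial_sample()] object; the raw (uncensored) response is
#'   written to `y`.
#' @export
write_sites_csv <- function(sample, path) {
  df <- dplyr::select(sample$data, "site_id", "u", "v", y = "response",
                      dplyr::all_of(sample$covariate_names))
  readr::write_csv(df, path)
  invisible(path)
}
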