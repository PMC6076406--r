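#' Min-max rescale a development component over the whole study period
#'
#' Each Socio-demographic Index component is rescaled to \[0, 1\] with 0 the
#' worst and 1 the best value observed across *all* location-years pooled.
#' For income and education higher is better (`direction = "ascending"`);
#' for total fertility rate lower is better (`direction = "descending"`).
#'
#' @param values numeric vector over all location-years
#' @param direction `"ascending"` (higher raw value maps to 1) or
#'   `"descending"` (lower raw value maps to 1)
#' @return rescaled values in \[0, 1\]
#' @examples
#' rescale_component(c(2, 4, 6))                 # 0, 0.5, 1
#' rescale_component(c(2, 4, 6), "descending")   # 1, 0.5, 0
#' @export
rescale_component <- function(values, direction = c("ascending",
                                                    "descending")) {
  direction <- match.arg(direction)
  rng <- range(values)
  if (diff(rng) == 0) {
    stop("constant component series: rescale undefined", call. = FALSE)
  }
  x <- (values - rng[1]) / diff(rng)
  if (direction == "descending") 1 - x else x
}

#' Socio-demographic Index from rescaled components
#'
#' Geometric mean of the three rescaled components (lag-distributed income
#' per capita, educational attainment, inverted total fertility rate).  Any
#' zero component gives an SDI of zero.
#'
#' @param income,education,fertility rescaled components in \[0, 1\]
#'   (fertility already inverted so 1 is best)
#' @return SDI values in \[0, 1\]
#' @examples
#' compute_sdi(0.25, 0.5, 1)  # 0.5
#' @export
compute_sdi <- function(income, education, fertility) {
  if (any(income < 0) || any(education < 0) || any(fertility < 0)) {
    stop("rescaled components must be non-negative", call. = FALSE)
  }
  (income * education * fertility)^(1 / 3)
}

#' SDI panel from raw development covariates
#'
#' Computes lag-distributed income, rescales the three components over the
#' pooled study period, and takes their geometric mean per location-year.
#'
#' @param covariates tibble with `location_id`, `year`,
#'   `income_per_capita`, `education_years`, `tfr`
#' @return the covariate tibble with an added `sdi` column
#' @export
sdi_panel <- function(covariates) {
  covs <- lag_distributed_income(covariates)
  covs$sdi <- compute_sdi(rescale_component(covs$ldi),
                          rescale_component(covs$education_years),
                          rescale_component(covs$tfr, "descending"))
  covs
}

SDI_LEVELS <- c("low", "lower-middle", "middle", "upper-middle", "high")

#' Assign development quintiles from SDI at a reference year
#'
#' Locations are ranked by SDI and split into five groups of near-equal
#' size (differing by at most one location): low, lower-middle, middle,
#' upper-middle, high.  Ties are broken by location id in lexicographic
#' order, so the assignment is reproducible and permutation-stable.
#' Membership is computed at one reference year and held fixed across the
#' series for trend reporting.
#'
#' @param sdi_values SDI per location at the reference year
#' @param location_ids matching location ids
#' @return tibble `location_id`, `sdi`, `level` (ordered factor)
#' @export
assign_quintiles <- function(sdi_values, location_ids) {
  n <- length(sdi_values)
  if (n < 5) stop("need at least 5 locations for quintiles", call. = FALSE)
  if (length(location_ids) != n) {
    stop("sdi_values and location_ids lengths differ", call. = FALSE)
  }
  ord <- order(sdi_values, location_ids)
  group <- integer(n)
  group[ord] <- ceiling(seq_len(n) * 5 / n)
  tibble::tibble(location_id = location_ids, sdi = sdi_values,
                 level = factor(SDI_LEVELS[group], levels = SDI_LEVELS,
                                ordered = TRUE))
}

#' Population-weighted availability by development level
#'
#' Aggregates a nutrient panel to per-level and global series as
#' population-weighted means — the only aggregation consistent with
#' reporting per-person national values at higher scopes.
#'
#' @param panel long availability panel (`location_id`, `year`,
#'   `nutrient_id`, `value`)
#' @param quintiles tibble `location_id`, `level` (see
#'   [assign_quintiles()])
#' @param population tibble `location_id`, `year`, `population`
#' @return tibble `scope` (`"global"` or a level name), `year`,
#'   `nutrient_id`, `value`
#' @export
aggregate_by_level <- function(panel, quintiles, population) {
  dat <- panel |>
    dplyr::inner_join(population[, c("location_id", "year", "population")],
                      by = c("location_id", "year")) |>
    dplyr::inner_join(quintiles[, c("location_id", "level")],
                      by = "location_id")
  if (nrow(dat) < nrow(panel)) {
    stop("population or quintile missing for some panel cells", call. = FALSE)
  }
  by_level <- dat |>
    dplyr::group_by(scope = as.character(.data$level), .data$year,
                    .data$nutrient_id) |>
    dplyr::summarise(value = sum(.data$value * .data$population) /
                       sum(.data$population), .groups = "drop")
  global <- dat |>
    dplyr::group_by(.data$year, .data$nutrient_id) |>
    dplyr::summarise(value = sum(.data$value * .data$population) /
                       sum(.data$population), .groups = "drop") |>
    dplyr::mutate(scope = "global", .before = 1)
  dplyr::bind_rows(global, by_level)
}
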