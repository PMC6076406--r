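#' Net change of a series between two years
#'
#' Endpoint difference `value(year_end) - value(year_start)`; both years
#' must be present.  If the series carries a `unit` column it must be
#' constant.
#'
#' @param series tibble with `year`, `value` (and optionally `unit`)
#' @param year_start,year_end endpoint years
#' @return the net change (a number)
#' @examples
#' absolute_change(data.frame(year = c(1980, 2013), value = c(2390, 2710)))
#' # 320
#' @export
absolute_change <- function(series, year_start = 1980, year_end = 2013) {
  if ("unit" %in% names(series)) {
    check_same_unit(series$unit, series$unit, "absolute_change")
  }
  v0 <- series$value[series$year == year_start]
  v1 <- series$value[series$year == year_end]
  if (length(v0) != 1 || length(v1) != 1) {
    stop("series must contain exactly one value for each endpoint year",
         call. = FALSE)
  }
  v1 - v0
}

#' Trend report: start/end values, net changes, start/end shares
#'
#' One row per scope and nutrient, summarising a (typically aggregated)
#' panel between two endpoint years.  `net_change` always equals
#' `value_end - value_start`.  Shares are percent of total energy and only
#' populated for macronutrient energies.
#'
#' @param agg aggregated panel: `scope`, `year`, `nutrient_id`, `value`
#' @param year_start,year_end endpoint years
#' @return tibble `scope`, `nutrient_id`, `value_start`, `value_end`,
#'   `net_change`, `share_start`, `share_end`
#' @export
trend_report <- function(agg, year_start = 1980, year_end = 2013) {
  ends <- agg |>
    dplyr::filter(.data$year %in% c(year_start, year_end)) |>
    tidyr::pivot_wider(names_from = "year", values_from = "value",
                       names_prefix = "y")
  v0 <- paste0("y", year_start); v1 <- paste0("y", year_end)
  if (!all(c(v0, v1) %in% names(ends))) {
    stop("endpoint year missing from aggregated panel", call. = FALSE)
  }
  energy <- ends[ends$nutrient_id == "energy_kcal", ]
  out <- ends |>
    dplyr::left_join(energy[, c("scope", v0, v1)],
                     by = "scope", suffix = c("", "_energy"))
  share_ok <- grepl("_kcal$", out$nutrient_id) &
    out$nutrient_id != "energy_kcal"
  tibble::tibble(
    scope = out$scope, nutrient_id = out$nutrient_id,
    value_start = out[[v0]], value_end = out[[v1]],
    net_change = out[[v1]] - out[[v0]],
    share_start = ifelse(share_ok,
                         100 * out[[v0]] / out[[paste0(v0, "_energy")]], NA),
    share_end = ifelse(share_ok,
                       100 * out[[v1]] / out[[paste0(v1, "_energy")]], NA))
}

# Pearson correlation matrix with two-sided p-values from the t transform.
pearson_matrix <- function(mat) {
  p <- ncol(mat)
  n <- nrow(mat)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(mat), colnames(mat)))
  pv <- r
  degenerate <- apply(mat, 2, function(x) sd(x) == 0)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (degenerate[i] || degenerate[j]) next  # undefined-correlation flag
      r[i, j] <- cor(mat[, i], mat[, j])
      if (i == j) { pv[i, j] <- 0; next }
      tstat <- r[i, j] * sqrt((n - 2) / (1 - r[i, j]^2))
      pv[i, j] <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  diag(r)[!degenerate] <- 1
  list(r = r, p = pv, n = n)
}

#' Cross-country correlations of macronutrient energy shares
#'
#' Pearson correlation, across locations at a fixed year, between the
#' percent of energy available from each pair of macronutrients.  Strong
#' negative correlations (for example carbohydrate share against
#' monounsaturated-fat share) indicate substitution patterns across the
#' development spectrum.  Pairs involving a zero-variance share are left
#' `NA` (undefined).  P-values are two-sided from the t transform,
#' unadjusted.
#'
#' @param panel long availability panel containing macronutrient `_kcal`
#'   entries and `energy_kcal`
#' @param year the cross-sectional year (default: last year in the panel)
#' @param macros macronutrients to correlate
#' @return list with matrices `r` and `p`, and `n` (number of locations)
#' @export
share_correlation_matrix <- function(panel, year = max(panel$year),
                                     macros = c("carbohydrate", "protein",
                                                "fat", "mufa", "pufa",
                                                "sfa")) {
  shares <- energy_shares_panel(panel[panel$year == year, ]) |>
    dplyr::filter(.data$nutrient %in% macros) |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "share_pct")
  if (nrow(shares) < 3) stop("need >= 3 locations", call. = FALSE)
  mat <- as.matrix(shares[, intersect(macros, names(shares))])
  pearson_matrix(mat)
}

#' Cross-country correlations of absolute nutrient availability
#'
#' As [share_correlation_matrix()] but on absolute per-capita availability
#' values rather than energy shares.
#'
#' @param panel long availability panel
#' @param nutrients nutrient ids to correlate
#' @param year the cross-sectional year (default: last year in the panel)
#' @return list with matrices `r` and `p`, and `n`
#' @export
availability_correlations <- function(panel,
                                      nutrients = c("carbohydrate_g",
                                                    "protein_g", "fat_g"),
                                      year = max(panel$year)) {
  wide <- panel |>
    dplyr::filter(.data$year == !!year, .data$nutrient_id %in% nutrients) |>
    dplyr::select("location_id", "nutrient_id", "value") |>
    tidyr::pivot_wider(names_from = "nutrient_id", values_from = "value")
  if (nrow(wide) < 3) stop("need >= 3 locations", call. = FALSE)
  mat <- as.matrix(wide[, intersect(nutrients, names(wide))])
  pearson_matrix(mat)
}
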