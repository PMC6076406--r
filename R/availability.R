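# Unit attached to each nutrient id in a long availability panel.
nutrient_unit <- function(nutrient_id) {
  dplyr::case_when(
    grepl("_kcal$", nutrient_id) ~ "kcal/person/day",
    grepl("_ug$", nutrient_id)   ~ "ug/person/day",
    grepl("_mg$", nutrient_id)   ~ "mg/person/day",
    grepl("_g$", nutrient_id)    ~ "g/person/day",
    TRUE ~ "unknown"
  )
}

#' Convert raw annual tonnage to per-capita daily grams
#'
#' Supply ledgers often report tonnes per year alongside population; the
#' analysis works in g/person/day.  A year is taken as 365.25 days.
#'
#' @param raw_tonnes_per_year tonnes of the commodity per year (>= 0)
#' @param population mid-year population (> 0)
#' @return g/person/day
#' @examples
#' per_capita_supply(365.25, 1e6)  # 1
#' @export
per_capita_supply <- function(raw_tonnes_per_year, population) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (any(raw_tonnes_per_year < 0)) {
    stop("raw tonnage must be non-negative", call. = FALSE)
  }
  raw_tonnes_per_year * 1e6 / population / 365.25
}

#' Per-capita nutrient contribution of one food item
#'
#' Gross supply is trimmed to its edible portion and scaled by the item's
#' nutrient density (per 100 g edible portion).
#'
#' @param gross_g_per_person_day gross supply of the item, g/person/day
#' @param record the item's composition row (one row)
#' @param nutrient_id composition column naming the nutrient density, e.g.
#'   `"protein_g"` or `"iron_mg"`
#' @return per-capita nutrient rate in the nutrient's unit per person/day
#' @examples
#' rec <- data.frame(item_id = "x", refuse_fraction = 0.3, energy_kcal = 80,
#'                   protein_g = 20, fat_g = 0, mufa_g = 0, pufa_g = 0,
#'                   sfa_g = 0, alcohol_g = 0)
#' item_nutrient_contribution(100, rec, "protein_g")  # 14
#' @export
item_nutrient_contribution <- function(gross_g_per_person_day, record,
                                       nutrient_id) {
  if (!nutrient_id %in% names(record)) {
    stop("unknown nutrient column: ", nutrient_id, call. = FALSE)
  }
  edible_fraction_mass(gross_g_per_person_day, record$refuse_fraction) *
    record[[nutrient_id]] / 100
}

# Composition columns that are nutrient densities (everything numeric
# except the refuse factor); the engine is nutrient-agnostic and iterates
# whatever density columns the table carries.
density_columns <- function(composition) {
  num <- vapply(composition, is.numeric, logical(1))
  setdiff(names(composition)[num], c("refuse_fraction"))
}

#' Aggregate a supply panel into a national nutrient-availability panel
#'
#' For every (location, year) the per-capita availability of each nutrient
#' is the sum over food items of edible supply times nutrient density.
#' Digestible carbohydrate is computed per item by difference from the
#' item's stored energy, then total energy is re-derived from the
#' aggregated protein, carbohydrate, fat and alcohol masses via the Atwater
#' factors, and macronutrient energies (`protein_kcal`, `carbohydrate_kcal`,
#' `fat_kcal`, `mufa_kcal`, `pufa_kcal`, `sfa_kcal`, `alcohol_kcal`) are
#' reported alongside the masses.  A location-year with no supply rows is
#' simply absent from the result (unobserved — never a silent zero).
#'
#' @param supply data frame with `location_id`, `year`, `item_id`,
#'   `gross_supply_g_per_person_day`
#' @param composition composition table (see [validate_composition()])
#' @param match matching table (`supply_item_id`, `composition_item_id`);
#'   defaults to the identity mapping on the composition ids
#' @param check_matching validate the matching table first and stop on
#'   unmatched items (default TRUE)
#' @return a long tibble — the availability panel — with columns
#'   `location_id`, `year`, `nutrient_id`, `value`, `unit`, `observed`
#' @export
aggregate_availability <- function(supply, composition, match = NULL,
                                   check_matching = TRUE) {
  if (is.null(match)) {
    match <- tibble::tibble(supply_item_id = composition$item_id,
                            composition_item_id = composition$item_id)
  }
  if (check_matching) {
    rep <- validate_matching(match, unique(supply$item_id), composition)
    if (!rep$ok) {
      stop("matching validation failed: ",
           length(rep$unmatched), " unmatched, ",
           length(rep$dangling), " dangling, ",
           length(rep$duplicated_supply_ids), " duplicated supply ids",
           call. = FALSE)
    }
  }
  validate_composition(composition)
  comp <- composition
  comp$carbohydrate_g <- suppressWarnings(carbohydrate_by_difference(comp))

  dens_cols <- density_columns(comp)
  dens_cols <- setdiff(dens_cols, "energy_kcal")  # energy re-derived below

  joined <- supply |>
    dplyr::inner_join(match, by = c(item_id = "supply_item_id")) |>
    dplyr::inner_join(comp, by = c(composition_item_id = "item_id"),
                      suffix = c("", ".comp"))
  edible <- edible_fraction_mass(joined$gross_supply_g_per_person_day,
                                 joined$refuse_fraction)
  contrib <- joined[, c("location_id", "year")]
  for (col in dens_cols) contrib[[col]] <- edible * joined[[col]] / 100

  agg <- contrib |>
    dplyr::group_by(.data$location_id, .data$year) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(dens_cols), sum),
                     .groups = "drop")

  agg$energy_kcal <- atwater_energy(agg$protein_g, agg$carbohydrate_g,
                                    agg$fat_g, agg$alcohol_g)
  for (m in c("protein", "carbohydrate", "alcohol")) {
    agg[[paste0(m, "_kcal")]] <- ATWATER[[m]] * agg[[paste0(m, "_g")]]
  }
  for (m in c("fat", "mufa", "pufa", "sfa")) {
    agg[[paste0(m, "_kcal")]] <- ATWATER[["fat"]] * agg[[paste0(m, "_g")]]
  }

  long <- agg |>
    tidyr::pivot_longer(-c("location_id", "year"),
                        names_to = "nutrient_id", values_to = "value")
  long$unit <- nutrient_unit(long$nutrient_id)
  long$observed <- TRUE
  dplyr::arrange(long, .data$nutrient_id, .data$location_id, .data$year)
}

#' Macronutrient energy shares for one panel cell
#'
#' Percent of total energy contributed by each macronutrient in a given
#' location-year.  When total energy is the Atwater sum of the four
#' macronutrients, the carbohydrate + protein + fat + alcohol shares close
#' to exactly 100.  MUFA/PUFA/SFA sub-shares are reported when present.
#'
#' @param panel long availability panel (see [aggregate_availability()])
#' @param location,year the cell to evaluate
#' @return tibble with `nutrient` (macronutrient name) and `share_pct`
#' @export
energy_shares <- function(panel, location, year) {
  cell <- panel[panel$location_id == location & panel$year == year, ]
  if (nrow(cell) == 0) stop("no panel entries for that location-year", call. = FALSE)
  total <- cell$value[cell$nutrient_id == "energy_kcal"]
  if (length(total) != 1 || is.na(total)) {
    stop("cell lacks an energy_kcal entry", call. = FALSE)
  }
  if (total <= 0) stop("energy is zero: shares undefined", call. = FALSE)
  macros <- c("carbohydrate", "protein", "fat", "mufa", "pufa", "sfa",
              "alcohol")
  kcal_ids <- paste0(macros, "_kcal")
  present <- kcal_ids %in% cell$nutrient_id
  vals <- vapply(kcal_ids[present], function(id) {
    cell$value[cell$nutrient_id == id][1]
  }, numeric(1))
  tibble::tibble(nutrient = macros[present],
                 share_pct = 100 * unname(vals) / total)
}

#' Energy shares for every cell of a panel
#'
#' Vectorised companion of [energy_shares()]: one row per
#' location-year-macronutrient.
#'
#' @param panel long availability panel
#' @return tibble with `location_id`, `year`, `nutrient`, `share_pct`
#' @export
energy_shares_panel <- function(panel) {
  macros <- c("carbohydrate", "protein", "fat", "mufa", "pufa", "sfa",
              "alcohol")
  wide <- panel |>
    dplyr::filter(.data$nutrient_id %in% c("energy_kcal",
                                           paste0(macros, "_kcal"))) |>
    dplyr::select("location_id", "year", "nutrient_id", "value") |>
    tidyr::pivot_wider(names_from = "nutrient_id", values_from = "value")
  if (!"energy_kcal" %in% names(wide)) {
    stop("panel lacks energy_kcal entries", call. = FALSE)
  }
  out <- lapply(intersect(paste0(macros, "_kcal"), names(wide)), function(id) {
    tibble::tibble(location_id = wide$location_id, year = wide$year,
                   nutrient = sub("_kcal$", "", id),
                   share_pct = 100 * wide[[id]] / wide$energy_kcal)
  })
  if (!length(out)) {
    return(tibble::tibble(location_id = character(), year = integer(),
                          nutrient = character(), share_pct = numeric()))
  }
  dplyr::bind_rows(out)
}
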