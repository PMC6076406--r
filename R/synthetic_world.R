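#' Configuration for a synthetic nutrient world
#'
#' The generator emulates the statistical structure of national food-supply
#' accounts: a commodity list with Atwater-consistent compositions, a panel
#' of locations whose diets shift with development (carbohydrate energy
#' share falling, fat and protein shares rising), country-year missingness
#' including fully unobserved locations, and survey intake derived from
#' availability through a waste factor and an age/sex pattern.
#'
#' @param n_items number of food items (>= 5)
#' @param n_locations number of locations (>= 10)
#' @param years inclusive integer range of years (span >= 2)
#' @param n_super_regions number of super-regions locations are grouped into
#' @param missing_fraction fraction of location-years masked as unobserved,
#'   in \[0, 1)
#' @param waste_factor retail + household waste applied when deriving intake
#'   from availability, in \[0, 1)
#' @param supply_noise_sd SD of the multiplicative log-normal noise on item
#'   supply quantities (0 disables noise)
#' @param intake_noise_frac SD of survey-intake noise, as a fraction of the
#'   mean intake signal for the nutrient
#' @param seed integer root seed; all generator streams derive from it via
#'   [seed_child()]
#' @return a validated `world_config` list
#' @export
world_config <- function(n_items = 60, n_locations = 150,
                         years = 1980:2013, n_super_regions = 7,
                         missing_fraction = 0.2, waste_factor = 0.3,
                         supply_noise_sd = 0.05, intake_noise_frac = 0.1,
                         seed = 1L) {
  cfg <- list(n_items = n_items, n_locations = n_locations,
              years = as.integer(years), n_super_regions = n_super_regions,
              missing_fraction = missing_fraction,
              waste_factor = waste_factor,
              supply_noise_sd = supply_noise_sd,
              intake_noise_frac = intake_noise_frac,
              seed = as.integer(seed))
  for (f in c("n_items", "n_locations", "n_super_regions", "missing_fraction",
              "waste_factor", "supply_noise_sd", "intake_noise_frac", "seed")) {
    stopifnot_scalar_number(cfg[[f]], f)
  }
  if (cfg$n_items < 5) abort_field("n_items", "must be >= 5")
  if (cfg$n_locations < 10) abort_field("n_locations", "must be >= 10")
  if (length(cfg$years) < 2) abort_field("years", "must span >= 2 years")
  if (any(diff(cfg$years) != 1L)) abort_field("years", "must be consecutive")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1) {
    abort_field("missing_fraction", "must lie in [0, 1)")
  }
  if (cfg$waste_factor < 0 || cfg$waste_factor >= 1) {
    abort_field("waste_factor", "must lie in [0, 1)")
  }
  if (cfg$n_super_regions < 1 || cfg$n_super_regions > cfg$n_locations) {
    abort_field("n_super_regions", "must be in [1, n_locations]")
  }
  structure(cfg, class = "world_config")
}

# Stream indices for seed_child(): 1 composition, 2 supply, 3 covariates,
# 4 intake, 5 location profiles, 6 age/sex pattern.

#' Generate a synthetic food-composition table
#'
#' Items fall into four broad classes (carbohydrate-rich staples, fat-rich,
#' protein-rich, alcoholic) whose macronutrient densities per 100 g edible
#' portion are drawn accordingly.  Total energy is set *forward* as the
#' Atwater sum `4 P + 9 F + 4 C + 7 A`, so that carbohydrate-by-difference
#' is exactly invertible; the forward-generated digestible carbohydrate is
#' recorded as ground truth.  Fat subtypes (MUFA/PUFA/SFA) are a random
#' partition of total fat.  Refuse fractions are drawn in \[0, 0.6\].
#'
#' @param config a [world_config()]
#' @return list with `composition` (tibble, one row per item, including a
#'   `true_carbohydrate_g` ground-truth column and an `item_class` label)
#'   and `matching` (identity matching table with duplicate coder columns)
#' @export
generate_composition_table <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(seed_child(config$seed, 1))
  n <- config$n_items
  classes <- sample(c("carb", "fat", "protein", "alcohol"), n, replace = TRUE,
                    prob = c(0.45, 0.25, 0.25, 0.05))
  protein <- fat <- carb <- alcohol <- numeric(n)
  for (i in seq_len(n)) {
    switch(classes[i],
      carb = {
        carb[i] <- runif(1, 40, 85); protein[i] <- runif(1, 1, 10)
        fat[i] <- runif(1, 0, 5)
      },
      fat = {
        fat[i] <- runif(1, 12, 45); carb[i] <- runif(1, 0, 20)
        protein[i] <- runif(1, 0, 15)
      },
      protein = {
        protein[i] <- runif(1, 10, 30); fat[i] <- runif(1, 2, 20)
        carb[i] <- runif(1, 0, 5)
      },
      alcohol = {
        alcohol[i] <- runif(1, 3, 12); carb[i] <- runif(1, 0, 10)
        protein[i] <- runif(1, 0, 1)
      })
  }
  # random partition of total fat into MUFA/PUFA/SFA
  g <- matrix(rgamma(3 * n, shape = 2), ncol = 3)
  frac <- g / rowSums(g)
  comp <- tibble::tibble(
    item_id = sprintf("item_%03d", seq_len(n)),
    item_class = classes,
    refuse_fraction = round(runif(n, 0, 0.6) * rbinom(n, 1, 0.7), 4),
    protein_g = round(protein, 3),
    fat_g = round(fat, 3),
    mufa_g = round(frac[, 1] * round(fat, 3), 6),
    pufa_g = round(frac[, 2] * round(fat, 3), 6),
    alcohol_g = round(alcohol, 3),
    true_carbohydrate_g = round(carb, 3),
    iron_mg = round(runif(n, 0.2, 8), 3),
    zinc_mg = round(runif(n, 0.2, 6), 3),
    vita_rae_ug = round(runif(n, 1, 300), 2)
  )
  comp$sfa_g <- comp$fat_g - comp$mufa_g - comp$pufa_g
  comp$energy_kcal <- atwater_energy(comp$protein_g, comp$true_carbohydrate_g,
                                     comp$fat_g, comp$alcohol_g)
  matching <- tibble::tibble(supply_item_id = comp$item_id,
                             composition_item_id = comp$item_id,
                             coder_a = comp$item_id, coder_b = comp$item_id)
  list(composition = comp, matching = matching)
}

# Deterministic location profiles shared by the supply and covariate
# generators: a development score per location-year that trends upward,
# and a super-region assignment (round-robin over development rank).
location_profiles <- function(config) {
  set.seed(seed_child(config$seed, 5))
  n <- config$n_locations
  yrs <- config$years
  base <- sort(runif(n, 0.02, 0.85))
  slope <- runif(n, 0.03, 0.18)  # development gained over the study period
  loc_ids <- sprintf("L%03d", seq_len(n))
  sr <- sprintf("SR%d", ((rank(base, ties.method = "first") - 1) %%
                           config$n_super_regions) + 1)
  grid <- expand.grid(location_id = loc_ids, year = yrs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(grid$location_id, loc_ids)
  frac <- (grid$year - yrs[1]) / (length(yrs) - 1)
  grid$development <- pmin(base[idx] + slope[idx] * frac, 0.99)
  grid$super_region <- sr[idx]
  tibble::as_tibble(grid[order(grid$location_id, grid$year), ])
}

# Item-mix log-weight slopes on development, by item class.  Negative for
# carbohydrate staples, positive for fat/protein-rich foods: as development
# rises the carbohydrate energy share falls and fat/protein shares rise.
DIET_TREND_COEF <- c(carb = -1.6, fat = 1.6, protein = 1.1, alcohol = 0.6)

#' Generate a synthetic food-supply panel with missingness
#'
#' Per-capita gross supply (g/person/day) of every item in every
#' location-year.  The item mix shifts deterministically with the location's
#' development score: item weights are proportional to
#' `exp(trend(class) * development)`, with negative trend for carbohydrate
#' staples and positive trends for fat- and protein-rich items (coefficients
#' recorded in the ground truth).  Total gross food mass also grows with
#' development.  Quantities get multiplicative log-normal noise
#' (`supply_noise_sd`).  A fraction `missing_fraction` of location-years is
#' masked as unobserved; part of the budget is spent on whole locations with
#' no observations at all, emulating countries absent from the source
#' accounts.
#'
#' @param config a [world_config()]
#' @param composition composition table from [generate_composition_table()]
#' @return list with `supply` (complete panel), `mask` (location-year tibble
#'   with `observed`), `observed_supply` (supply restricted to observed
#'   cells) and `profiles` (development scores and super-regions)
#' @export
generate_supply_panel <- function(config, composition) {
  stopifnot(inherits(config, "world_config"))
  if (nrow(composition) != config$n_items) {
    stop("composition table has ", nrow(composition),
         " items but config expects ", config$n_items, call. = FALSE)
  }
  profiles <- location_profiles(config)
  set.seed(seed_child(config$seed, 2))

  trend <- DIET_TREND_COEF[composition$item_class]
  # item popularity: staples dominate the food basket by mass
  popularity <- c(carb = 6, fat = 0.6, protein = 0.9, alcohol = 0.25)
  base_w <- popularity[composition$item_class] *
    runif(config$n_items, 0.5, 1.5)
  # total gross food mass rises with development
  n_cell <- nrow(profiles)
  total_g <- 950 + 550 * profiles$development

  logw <- outer(profiles$development, trend) +
    matrix(log(base_w), n_cell, config$n_items, byrow = TRUE)
  w <- exp(logw)
  w <- w / rowSums(w)
  qty <- w * total_g
  if (config$supply_noise_sd > 0) {
    s <- config$supply_noise_sd
    noise <- matrix(rlnorm(n_cell * config$n_items,
                           meanlog = -s^2 / 2, sdlog = s),
                    n_cell, config$n_items)
    qty <- qty * noise
  }
  supply <- tibble::tibble(
    location_id = rep(profiles$location_id, config$n_items),
    year = rep(profiles$year, config$n_items),
    item_id = rep(composition$item_id, each = n_cell),
    gross_supply_g_per_person_day = as.vector(qty)
  ) |> dplyr::arrange(.data$location_id, .data$year, .data$item_id)

  # missingness: whole-location gaps first, then random location-years
  loc_ids <- unique(profiles$location_id)
  n_years <- length(config$years)
  n_cells <- config$n_locations * n_years
  n_missing <- round(config$missing_fraction * n_cells)
  n_whole <- min(floor(0.05 * config$n_locations), n_missing %/% n_years)
  whole_locs <- if (n_whole > 0) sample(loc_ids, n_whole) else character()
  mask <- profiles[, c("location_id", "year")]
  mask$observed <- TRUE
  mask$observed[mask$location_id %in% whole_locs] <- FALSE
  remainder <- n_missing - n_whole * n_years
  if (remainder > 0) {
    candidates <- which(mask$observed)
    mask$observed[sample(candidates, remainder)] <- FALSE
  }
  observed_cells <- mask[mask$observed, c("location_id", "year")]
  observed_supply <- dplyr::semi_join(supply, observed_cells,
                                      by = c("location_id", "year"))
  list(supply = supply, mask = mask, observed_supply = observed_supply,
       profiles = profiles)
}

#' Generate development covariates (income, education, fertility)
#'
#' Income per capita rises exponentially with the development score,
#' educational attainment rises linearly, and the total fertility rate
#' falls; all three are strictly positive and carry small log-normal /
#' Gaussian noise.  A population column (persons) is included for
#' population-weighted aggregation.
#'
#' @param config a [world_config()]
#' @return covariate tibble: `location_id`, `year`, `super_region`,
#'   `development`, `income_per_capita`, `education_years`, `tfr`,
#'   `population`
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "world_config"))
  profiles <- location_profiles(config)
  set.seed(seed_child(config$seed, 3))
  n <- nrow(profiles)
  loc_ids <- unique(profiles$location_id)
  idx <- match(profiles$location_id, loc_ids)
  pop_base <- rlnorm(length(loc_ids), meanlog = 15.5, sdlog = 1.2)
  pop_growth <- runif(length(loc_ids), 0.002, 0.025)
  covariates <- tibble::tibble(
    location_id = profiles$location_id,
    year = profiles$year,
    super_region = profiles$super_region,
    development = profiles$development,
    income_per_capita = exp(6.3 + 3.4 * profiles$development +
                              rnorm(n, 0, 0.12)),
    education_years = pmax(0.5, 1 + 12 * profiles$development +
                             rnorm(n, 0, 0.3)),
    tfr = pmax(0.8, 6.8 - 5.4 * profiles$development + rnorm(n, 0, 0.15)),
    population = pop_base[idx] *
      exp(pop_growth[idx] * (profiles$year - config$years[1]))
  )
  covariates
}

#' Default age/sex intake pattern
#'
#' Multipliers per (age group, sex) drawn around 1 and normalised so the
#' population-weighted mean over groups equals 1 (equal weights by
#' default): applying the pattern redistributes a national value across
#' demographic groups without changing its population mean.
#'
#' @param config a [world_config()]
#' @param age_groups character vector of age-group labels
#' @param sexes character vector of sex labels
#' @return tibble `age_group`, `sex`, `multiplier`, `weight`
#' @export
generate_age_sex_pattern <- function(config,
                                     age_groups = c("2-19", "20-34", "35-49",
                                                    "50-64", "65+"),
                                     sexes = c("female", "male")) {
  stopifnot(inherits(config, "world_config"))
  set.seed(seed_child(config$seed, 6))
  grid <- expand.grid(age_group = age_groups, sex = sexes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- rlnorm(nrow(grid), 0, 0.25)
  w <- rep(1 / nrow(grid), nrow(grid))
  m <- m / sum(m * w)                      # weighted mean exactly 1
  tibble::tibble(age_group = grid$age_group, sex = grid$sex,
                 multiplier = m, weight = w)
}

#' Simulate survey-derived mean nutrient intake
#'
#' Intake for location c, age a, sex s, year t is
#' `beta * availability(c,t) * multiplier(a,s) * (1 - waste_factor)`
#' plus an additive age effect, sex effect, super-region intercept and
#' Gaussian noise.  The waste factor represents retail and household losses
#' between national availability and what surveys record as consumed.
#'
#' @param config a [world_config()]
#' @param availability_panel long availability panel restricted to the
#'   nutrients to simulate (complete for the sampled location-years)
#' @param pattern age/sex pattern tibble (see [generate_age_sex_pattern()])
#' @param true_beta intake-availability slope before waste adjustment
#' @param super_regions tibble `location_id`, `super_region`
#' @param effect_sd_age,effect_sd_sex,effect_sd_super_region SDs of the
#'   additive demographic and regional effects (0 disables an effect)
#' @return list with `intake` tibble (`location_id`, `year`, `age_group`,
#'   `sex`, `nutrient_id`, `mean_intake`) and `params` (all effects used)
#' @export
generate_survey_intake <- function(config, availability_panel, pattern,
                                   true_beta = 0.95, super_regions = NULL,
                                   effect_sd_age = 0.5, effect_sd_sex = 0.5,
                                   effect_sd_super_region = 1) {
  stopifnot(inherits(config, "world_config"))
  need <- c("age_group", "sex", "multiplier", "weight")
  if (!all(need %in% names(pattern))) {
    stop("pattern must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(super_regions)) {
    profiles <- location_profiles(config)
    super_regions <- dplyr::distinct(profiles, .data$location_id,
                                     .data$super_region)
  }
  set.seed(seed_child(config$seed, 4))
  n_groups <- nrow(pattern)
  age_levels <- unique(pattern$age_group)
  sex_levels <- unique(pattern$sex)
  sr_levels <- sort(unique(super_regions$super_region))
  age_eff <- setNames(rnorm(length(age_levels), 0, effect_sd_age), age_levels)
  age_eff <- age_eff - age_eff[1]             # first group is reference
  sex_eff <- setNames(c(0, rnorm(length(sex_levels) - 1, 0, effect_sd_sex)),
                      sex_levels)
  sr_eff <- setNames(rnorm(length(sr_levels), 0, effect_sd_super_region),
                     sr_levels)

  avail <- availability_panel |>
    dplyr::select("location_id", "year", "nutrient_id", "value") |>
    dplyr::inner_join(super_regions, by = "location_id")
  rows <- tidyr::crossing(avail, pattern[, c("age_group", "sex", "multiplier")])
  signal <- true_beta * rows$value * rows$multiplier *
    (1 - config$waste_factor)
  noise_sd <- tapply(signal, rows$nutrient_id, mean) * config$intake_noise_frac
  eps <- rnorm(nrow(rows), 0, noise_sd[rows$nutrient_id])
  intake <- tibble::tibble(
    location_id = rows$location_id, year = rows$year,
    age_group = rows$age_group, sex = rows$sex,
    nutrient_id = rows$nutrient_id,
    mean_intake = pmax(0, signal + age_eff[rows$age_group] +
                         sex_eff[rows$sex] + sr_eff[rows$super_region] + eps)
  )
  list(intake = intake,
       params = list(true_beta = true_beta,
                     effective_slope = true_beta * (1 - config$waste_factor),
                     age_effects = age_eff, sex_effects = sex_eff,
                     super_region_effects = sr_eff,
                     noise_sd = noise_sd))
}

#' Generate a complete synthetic world with ground truth
#'
#' Convenience wrapper running the four generators in sequence and
#' computing the ground-truth availability panel (complete, no missingness)
#' by pushing the complete supply panel through the accounting engine.
#'
#' @param config a [world_config()]
#' @param intake_nutrients nutrient ids to simulate survey intake for
#' @param true_beta intake-availability slope used in the intake simulator
#' @return list with `composition`, `matching`, `supply` (observed rows),
#'   `mask`, `covariates`, `intake`, `pattern`, and `ground_truth` (class
#'   `nutledger_ground_truth`): complete supply and availability panels,
#'   development profiles, diet trend coefficients, and intake parameters
#' @export
generate_world <- function(config = world_config(),
                           intake_nutrients = c("protein_g",
                                                "carbohydrate_g", "fat_g",
                                                "zinc_mg"),
                           true_beta = 0.95) {
  compo <- generate_composition_table(config)
  comp_public <- dplyr::select(compo$composition, -"true_carbohydrate_g",
                               -"item_class")
  sup <- generate_supply_panel(config, compo$composition)
  covariates <- generate_covariates(config)
  truth_panel <- aggregate_availability(sup$supply, comp_public,
                                        compo$matching)
  pattern <- generate_age_sex_pattern(config)
  intake_avail <- dplyr::filter(truth_panel,
                                .data$nutrient_id %in% intake_nutrients)
  intake <- generate_survey_intake(config, intake_avail, pattern,
                                   true_beta = true_beta)
  ground_truth <- structure(
    list(item_compositions = compo$composition,
         supply_complete = sup$supply,
         availability_complete = truth_panel,
         profiles = sup$profiles,
         diet_trend_coefficients = DIET_TREND_COEF,
         pattern = pattern,
         intake_params = intake$params,
         config = config),
    class = "nutledger_ground_truth")
  list(composition = comp_public, matching = compo$matching,
       supply = sup$observed_supply, mask = sup$mask,
       covariates = covariates, intake = intake$intake,
       pattern = pattern, ground_truth = ground_truth)
}
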