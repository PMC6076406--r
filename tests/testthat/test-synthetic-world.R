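test_that("world config validates its fields by name", {
  expect_error(world_config(n_items = 3), "n_items")
  expect_error(world_config(n_locations = 5), "n_locations")
  expect_error(world_config(years = 2000), "years")
  expect_error(world_config(missing_fraction = 1), "missing_fraction")
  expect_error(world_config(waste_factor = -0.1), "waste_factor")
})

test_that("composition generator is Atwater-consistent and seed-stable", {
  cfg <- tiny_config(n_items = 50, seed = 7)
  a <- generate_composition_table(cfg)
  b <- generate_composition_table(cfg)
  expect_identical(a, b)
  comp <- a$composition
  expect_equal(nrow(comp), 50)
  expect_true(all(comp$refuse_fraction >= 0 & comp$refuse_fraction <= 0.6))
  expect_lt(max(abs(comp$energy_kcal -
                      atwater_energy(comp$protein_g, comp$true_carbohydrate_g,
                                     comp$fat_g, comp$alcohol_g))), 1e-9)
  expect_lt(max(comp$mufa_g + comp$pufa_g + comp$sfa_g - comp$fat_g), 1e-6)
  expect_true(all(comp$iron_mg > 0 & comp$zinc_mg > 0 & comp$vita_rae_ug > 0))
})

test_that("missingness mask matches the configured fraction", {
  cfg0 <- tiny_config(missing_fraction = 0)
  comp <- generate_composition_table(cfg0)$composition
  sup0 <- generate_supply_panel(cfg0, comp)
  expect_true(all(sup0$mask$observed))

  cfg <- tiny_config(missing_fraction = 0.2)
  sup <- generate_supply_panel(cfg, generate_composition_table(cfg)$composition)
  n_cells <- nrow(sup$mask)
  expect_equal(sum(!sup$mask$observed), round(0.2 * n_cells))
  # observed supply is exactly the complete panel restricted to the mask
  rebuilt <- dplyr::semi_join(sup$supply, sup$mask[sup$mask$observed, ],
                              by = c("location_id", "year"))
  expect_identical(sup$observed_supply, rebuilt)
  # whole-location gaps are present (emulating countries with no accounts)
  per_loc <- tapply(sup$mask$observed, sup$mask$location_id, any)
  expect_true(any(!per_loc))
})

test_that("item-count mismatch between config and composition is an error", {
  cfg <- tiny_config(n_items = 12)
  comp <- generate_composition_table(tiny_config(n_items = 15))$composition
  expect_error(generate_supply_panel(cfg, comp), "15 items")
})

test_that("development raises the fat energy share in the noise-free world", {
  cfg <- tiny_config(n_locations = 20, supply_noise_sd = 0,
                     missing_fraction = 0)
  compo <- generate_composition_table(cfg)
  sup <- generate_supply_panel(cfg, compo$composition)
  panel <- aggregate_availability(
    sup$supply, dplyr::select(compo$composition, -"true_carbohydrate_g",
                              -"item_class"), compo$matching)
  dev <- sup$profiles[sup$profiles$year == min(cfg$years), ]
  lo <- dev$location_id[which.min(dev$development)]
  hi <- dev$location_id[which.max(dev$development)]
  shares <- energy_shares_panel(panel)
  fat <- shares[shares$nutrient == "fat", ]
  carb <- shares[shares$nutrient == "carbohydrate", ]
  for (y in cfg$years) {
    expect_gt(fat$share_pct[fat$location_id == hi & fat$year == y],
              fat$share_pct[fat$location_id == lo & fat$year == y])
    expect_lt(carb$share_pct[carb$location_id == hi & carb$year == y],
              carb$share_pct[carb$location_id == lo & carb$year == y])
  }
  # the recorded trend coefficients point the same way
  tc <- nutledger:::DIET_TREND_COEF
  expect_lt(tc[["carb"]], 0)
  expect_gt(tc[["fat"]], 0)
})

test_that("covariates track development and are seed-stable", {
  cfg <- tiny_config()
  cov1 <- generate_covariates(cfg)
  expect_identical(cov1, generate_covariates(cfg))
  expect_true(all(cov1$income_per_capita > 0 & cov1$education_years > 0 &
                    cov1$tfr > 0 & cov1$population > 0))
  yr <- cov1[cov1$year == 2000, ]
  expect_gt(cor(yr$income_per_capita, yr$development), 0.5)
  expect_gt(cor(yr$education_years, yr$development), 0.5)
  expect_lt(cor(yr$tfr, yr$development), -0.5)
  # most vs least developed location: monotone in every year
  lo <- yr$location_id[which.min(yr$development)]
  hi <- yr$location_id[which.max(yr$development)]
  a <- cov1[cov1$location_id == lo, ]; b <- cov1[cov1$location_id == hi, ]
  expect_true(all(b$income_per_capita > a$income_per_capita))
  expect_true(all(b$education_years > a$education_years))
  expect_true(all(b$tfr < a$tfr))
})

test_that("survey intake reduces to availability under the identity setting", {
  cfg <- tiny_config(waste_factor = 0, intake_noise_frac = 0)
  avail <- tibble::tibble(location_id = rep(c("L001", "L002"), each = 2),
                          year = rep(1990:1991, 2),
                          nutrient_id = "protein_g",
                          value = c(50, 55, 70, 72))
  pattern <- tibble::tibble(age_group = c("a", "b"), sex = "all",
                            multiplier = 1, weight = 0.5)
  out <- generate_survey_intake(cfg, avail, pattern, true_beta = 1,
                                effect_sd_age = 0, effect_sd_sex = 0,
                                effect_sd_super_region = 0)
  m <- dplyr::inner_join(out$intake, avail,
                         by = c("location_id", "year", "nutrient_id"))
  expect_equal(m$mean_intake, m$value)

  # a 30% waste factor scales intake to 0.7 x availability
  cfg2 <- tiny_config(waste_factor = 0.3, intake_noise_frac = 0)
  out2 <- generate_survey_intake(cfg2, avail, pattern, true_beta = 1,
                                 effect_sd_age = 0, effect_sd_sex = 0,
                                 effect_sd_super_region = 0)
  m2 <- dplyr::inner_join(out2$intake, avail,
                          by = c("location_id", "year", "nutrient_id"))
  expect_equal(m2$mean_intake, 0.7 * m2$value)
  expect_equal(out2$params$effective_slope, 0.7)
})

test_that("whole synthetic world reruns bit-identically from the root seed", {
  cfg <- tiny_config(n_locations = 12, years = 1995:2000)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$supply, w2$supply)
  expect_identical(w1$covariates, w2$covariates)
  expect_identical(w1$intake, w2$intake)
  expect_identical(w1$ground_truth$availability_complete,
                   w2$ground_truth$availability_complete)
  # ground truth is complete: every location-year-nutrient populated
  gt <- w1$ground_truth$availability_complete
  expect_equal(nrow(dplyr::distinct(gt, location_id, year)),
               12 * length(cfg$years))
  expect_false(anyNA(gt$value))
})
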