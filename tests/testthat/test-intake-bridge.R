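# matched availability/intake rows from a small synthetic world
matched_rows <- function(cfg, true_beta = 0.95, ...) {
  w <- generate_world(cfg, intake_nutrients = "protein_g",
                      true_beta = true_beta)
  avail <- w$ground_truth$availability_complete
  avail <- avail[avail$nutrient_id == "protein_g", ]
  by_group <- apply_age_sex_pattern(
    avail[, c("location_id", "year", "nutrient_id", "value")], w$pattern)
  srs <- dplyr::distinct(w$ground_truth$profiles, location_id, super_region)
  intake <- generate_survey_intake(cfg, avail, w$pattern,
                                   true_beta = true_beta, ...)
  rows <- dplyr::inner_join(
    intake$intake, by_group,
    by = c("location_id", "year", "age_group", "sex", "nutrient_id")) |>
    dplyr::inner_join(srs, by = "location_id") |>
    dplyr::rename(availability = "value", intake = "mean_intake")
  list(rows = rows, params = intake$params)
}

test_that("age/sex pattern application conserves the national mean", {
  avail <- tibble::tibble(location_id = "A", year = 2000,
                          nutrient_id = "protein_g", value = 80)
  flat <- tibble::tibble(age_group = c("y", "o"), sex = "all",
                         multiplier = 1, weight = 0.5)
  out <- apply_age_sex_pattern(avail, flat)
  expect_equal(out$value, c(80, 80))

  two <- flat; two$multiplier <- c(0.5, 1.5)
  out2 <- apply_age_sex_pattern(avail, two)
  expect_equal(sort(out2$value), c(40, 120))
  expect_equal(sum(out2$value * 0.5), 80)

  # renormalisation holds for arbitrary positive patterns and weights
  set.seed(12)
  for (i in 1:5) {
    pat <- tibble::tibble(age_group = rep(letters[1:4], 2),
                          sex = rep(c("f", "m"), each = 4),
                          multiplier = rlnorm(8, 0, 0.6),
                          weight = runif(8, 0.1, 1))
    o <- apply_age_sex_pattern(avail, pat)
    wmean <- sum(o$value * pat$weight[match(paste(o$age_group, o$sex),
                                            paste(pat$age_group, pat$sex))]) /
      sum(pat$weight)
    expect_equal(wmean, 80, tolerance = 1e-9)
  }

  groups <- tibble::tibble(age_group = c("y", "o", "x"), sex = "all")
  expect_error(apply_age_sex_pattern(avail, flat, groups), "missing group")
  bad <- flat; bad$multiplier <- c(1, -1)
  expect_error(apply_age_sex_pattern(avail, bad), "positive")
})

test_that("intake model recovers an exact linear generating process", {
  cfg <- tiny_config(n_locations = 15, years = 1998:2003,
                     missing_fraction = 0, waste_factor = 0.3,
                     intake_noise_frac = 0)
  mr <- matched_rows(cfg, true_beta = 1)
  fit <- fit_intake_model(mr$rows)
  # noise-free: the slope is the waste-adjusted generating slope, exactly
  expect_equal(fit$beta, 0.7, tolerance = 1e-6)
  expect_true(is.finite(fit$residual_sd))

  # permuting rows leaves the fit unchanged
  set.seed(2)
  fit2 <- fit_intake_model(mr$rows[sample(nrow(mr$rows)), ])
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-9)

  expect_error(fit_intake_model(mr$rows[1:10, ]), ">= 30 rows")
  one_sr <- mr$rows; one_sr$super_region <- "SR1"
  expect_error(fit_intake_model(one_sr), "super-region")
  collinear <- mr$rows; collinear$age_group <- collinear$sex
  expect_error(fit_intake_model(collinear), "collinear")
})

test_that("out-of-sample evaluation is deterministic and exact on clean data", {
  cfg <- tiny_config(n_locations = 15, years = 1998:2003,
                     missing_fraction = 0, intake_noise_frac = 0)
  rows <- matched_rows(cfg, true_beta = 1)$rows
  ev <- evaluate_out_of_sample(rows, "linear", "by-location", seed = 3)
  expect_lt(ev$rmse, 1e-6)
  expect_equal(ev$r, 1, tolerance = 1e-9)
  ev2 <- evaluate_out_of_sample(rows, "linear", "by-location", seed = 3)
  expect_identical(ev, ev2)
  expect_gt(evaluate_out_of_sample(rows, "linear", "by-year",
                                   seed = 1)$n_test, 0)
  expect_error(evaluate_out_of_sample(rows, "no-such-model"), "unknown")
})

test_that("a constant predictor flags the correlation and keeps honest RMSE", {
  cfg <- tiny_config(n_locations = 12, years = 2000:2002,
                     missing_fraction = 0)
  rows <- matched_rows(cfg)$rows
  register_regressor("constant",
                     fit = function(rows) mean(rows$intake),
                     predict = function(object, rows) {
                       rep(object, nrow(rows))
                     })
  ev <- evaluate_out_of_sample(rows, "constant", "random", seed = 7)
  expect_false(ev$r_defined)
  expect_true(is.na(ev$r))
  # oracle: recompute the split and the constant-model RMSE directly
  set.seed(7L)
  held <- sample(seq_len(nrow(rows)), max(1, round(0.2 * nrow(rows))))
  test_idx <- seq_len(nrow(rows)) %in% held
  expect_equal(ev$rmse,
               sqrt(mean((mean(rows$intake[!test_idx]) -
                            rows$intake[test_idx])^2)),
               tolerance = 1e-12)
})

test_that("linear model generalises to held-out locations under moderate noise", {
  cfg <- tiny_config(n_locations = 25, years = 1995:2004,
                     missing_fraction = 0, intake_noise_frac = 0.1)
  rows <- matched_rows(cfg)$rows
  ev <- evaluate_out_of_sample(rows, "linear", "by-location", seed = 11)
  expect_gt(ev$r, 0.8)
})

test_that("tree-ensemble regressors run through the registry contract", {
  skip_if_not_installed("ranger")
  skip_if_not_installed("xgboost")
  cfg <- tiny_config(n_locations = 15, years = 2000:2003,
                     missing_fraction = 0, intake_noise_frac = 0.1)
  rows <- matched_rows(cfg)$rows
  expect_true(all(c("linear", "random_forest", "xgboost") %in%
                    list_regressors()))
  for (reg in c("random_forest", "xgboost")) {
    ev <- evaluate_out_of_sample(rows, reg, "random", seed = 5)
    expect_true(is.finite(ev$rmse))
    expect_gt(ev$r, 0.5)   # smoke check only; no seed-exact assertion
  }
})

test_that("share comparison is invariant to a uniform waste factor", {
  w <- generate_world(tiny_config(n_locations = 12, years = 2000:2004,
                                  missing_fraction = 0),
                      intake_nutrients = c("protein_g", "carbohydrate_g",
                                           "fat_g"))
  avail <- w$ground_truth$availability_complete
  macro <- avail[avail$nutrient_id %in% c("protein_g", "carbohydrate_g",
                                          "fat_g"), ]
  # intake exactly 0.7 x availability in one national age/sex cell
  intake <- macro |>
    dplyr::transmute(location_id, year, age_group = "all", sex = "all",
                     nutrient_id, mean_intake = 0.7 * value)
  cmp <- compare_energy_shares(macro, intake)
  expect_lt(max(cmp$diff_points), 1e-9)

  # shifting the intake protein share by exactly +3 points is reported as 3
  wide <- tidyr::pivot_wider(macro[, c("location_id", "year", "nutrient_id",
                                       "value")],
                             names_from = "nutrient_id",
                             values_from = "value")
  cell <- wide[1, ]
  total <- 4 * cell$protein_g + 4 * cell$carbohydrate_g + 9 * cell$fat_g
  p_share <- 100 * 4 * cell$protein_g / total
  p_new <- p_share + 3
  keep_ratio <- (100 - p_new) / (100 - p_share)
  intake1 <- tibble::tibble(
    location_id = cell$location_id, year = cell$year, age_group = "all",
    sex = "all",
    nutrient_id = c("protein_g", "carbohydrate_g", "fat_g"),
    mean_intake = c(p_new * total / 100 / 4,
                    cell$carbohydrate_g * keep_ratio,
                    cell$fat_g * keep_ratio))
  avail1 <- macro[macro$location_id == cell$location_id &
                    macro$year == cell$year, ]
  cmp1 <- compare_energy_shares(avail1, intake1)
  expect_equal(cmp1$diff_points[cmp1$nutrient == "protein"], 3,
               tolerance = 1e-9)
})

test_that("synthetic-world intake shares stay close to availability shares", {
  w <- generate_world(tiny_config(n_locations = 20, missing_fraction = 0),
                      intake_nutrients = c("protein_g", "carbohydrate_g",
                                           "fat_g", "alcohol_g"))
  p <- aggregate_availability(w$supply, w$composition, w$matching)
  cmp <- compare_energy_shares(p, w$intake,
                               weights = w$pattern[, c("age_group", "sex",
                                                       "weight")])
  expect_lt(max(cmp$diff_points), 5)
})
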