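make_covs <- function(n_loc = 5, years = 2000:2009, n_sr = 2, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(location_id = sprintf("L%02d", seq_len(n_loc)),
                      year = years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$super_region <- paste0("SR", (match(grid$location_id,
                                           unique(grid$location_id)) %%
                                       n_sr) + 1)
  grid$income_per_capita <- exp(rnorm(nrow(grid), 8, 0.3))
  tibble::as_tibble(grid)
}

test_that("lag-distributed income matches the stated weight formula", {
  covs <- tibble::tibble(location_id = "A", year = 2000:2014,
                         income_per_capita = 500)
  expect_equal(lag_distributed_income(covs)$ldi, rep(500, 15))
  one <- tibble::tibble(location_id = "A", year = 2000,
                        income_per_capita = 123)
  expect_equal(lag_distributed_income(one)$ldi, 123)

  # linear ramp against a direct weighted-sum oracle
  ramp <- tibble::tibble(location_id = "A", year = 2000:2019,
                         income_per_capita = 100 + 10 * (0:19))
  got <- lag_distributed_income(ramp)$ldi
  w <- 10:1
  oracle <- sapply(seq_len(20), function(t) {
    k <- seq_len(min(10, t))
    sum(w[k] * ramp$income_per_capita[t - k + 1]) / sum(w[k])
  })
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(lag_distributed_income(ramp[0, ]), "empty")
})

test_that("stage-1 prior is exact on noise-free linear data and covers unobserved locations", {
  covs <- lag_distributed_income(make_covs(n_loc = 8, n_sr = 2))
  sr_eff <- c(SR1 = 0, SR2 = 30)
  covs$value <- 10 + 5 * log(covs$ldi) + sr_eff[covs$super_region]
  obs <- covs[covs$location_id != "L01", c("location_id", "year", "value")]
  s1 <- stage1_prior(obs, covs)
  expect_lt(max(abs(s1$residuals$resid)), 1e-9)
  # the fully unobserved location sits exactly on its super-region line
  pr <- dplyr::inner_join(s1$prior, covs[, c("location_id", "year", "value")],
                          by = c("location_id", "year"))
  expect_lt(max(abs(pr$prior_mean - pr$value)), 1e-8)
  expect_error(stage1_prior(obs[0, ], covs, "iron_mg"), "iron_mg")
})

test_that("stage-1 recovers its coefficients within 2 SE under noise", {
  covs <- lag_distributed_income(make_covs(n_loc = 40, years = 1990:2009,
                                           n_sr = 4, seed = 5))
  set.seed(9)
  covs$value <- 20 + 4 * log(covs$ldi) + rnorm(nrow(covs), 0, 2)
  keep <- runif(nrow(covs)) > 0.2
  s1 <- stage1_prior(covs[keep, c("location_id", "year", "value")], covs)
  est <- summary(s1$fit)$coefficients["log_ldi", ]
  expect_lt(abs(est["Estimate"] - 4), 2 * est["Std. Error"])
})

test_that("stage-2 weights normalise and respect the spatial tiers", {
  grid <- make_covs(n_loc = 4, years = 2000:2004)[, c("location_id", "year",
                                                      "super_region")]
  # a single observed residual spreads everywhere unchanged
  single <- tibble::tibble(location_id = "L01", year = 2002,
                           super_region = "SR2", resid = 3.7)
  sm <- stage2_residual_smooth(single, grid, 0.5, 0.9)
  expect_equal(sm$smooth_resid, rep(3.7, nrow(grid)))

  # zeta = 1: a fully observed location depends only on its own residuals
  set.seed(1)
  res <- grid
  res$resid <- rnorm(nrow(res))
  sm1 <- stage2_residual_smooth(res, grid, 0.5, 1)
  own <- res[res$location_id == "L02", ]
  years <- sort(unique(grid$year))
  dmax <- max(years) - min(years)
  for (y in years) {
    k <- (1 - (abs(y - own$year) / (1 + dmax))^0.5)^3
    expect_equal(sm1$smooth_resid[sm1$location_id == "L02" & sm1$year == y],
                 sum(k * own$resid) / sum(k), tolerance = 1e-12)
  }
  expect_error(stage2_residual_smooth(res[0, ], grid, 0.5, 0.9), "residuals")
})

test_that("stage-2 matches the brute-force double loop", {
  set.seed(4)
  grid <- make_covs(n_loc = 5, years = 2001:2005,
                    n_sr = 2)[, c("location_id", "year", "super_region")]
  res <- grid[sample(nrow(grid), 15), ]
  res$resid <- rnorm(15)
  for (zeta in c(0.3, 0.9)) {
    got <- stage2_residual_smooth(res, grid, 0.7, zeta)
    expect_lt(max(abs(got$smooth_resid -
                        stage2_oracle(res, grid, 0.7, zeta))), 1e-12)
  }
})

test_that("stage-3 GP interpolates, falls back to the prior, and matches the closed form", {
  yrs <- 2000:2009
  prior <- rep(5, 10)
  obs_y <- c(2001, 2003, 2006, 2009)
  obs_v <- c(4, 6, 5.5, 7)
  p <- stgpr_params(gp_amplitude = 1.5, gp_length_scale_years = 4,
                    gp_nugget = 0.1, n_draws = 400, seed = 11)

  g <- stage3_gp(yrs, prior, obs_y, obs_v, p)
  oracle <- gp_oracle(yrs, prior, obs_y, obs_v, 1.5, 4, 0.1)
  expect_lt(max(abs(g$mean - oracle)), 1e-8)

  # vanishing nugget: posterior mean hits every observation
  p0 <- stgpr_params(gp_amplitude = 1.5, gp_length_scale_years = 4,
                     gp_nugget = 0, nugget_floor = 1e-10, n_draws = 400)
  g0 <- stage3_gp(yrs, prior, yrs, prior + sin(yrs), p0)
  expect_lt(max(abs(g0$mean - (prior + sin(yrs)))), 1e-6)

  # no observations: prior returned untouched
  gn <- stage3_gp(yrs, prior, integer(), numeric(), p)
  expect_identical(gn$mean, prior)
  expect_true(all(gn$upper > gn$lower))

  # draws are deterministic given the seed
  g2 <- stage3_gp(yrs, prior, obs_y, obs_v, p)
  expect_identical(g$draws, g2$draws)

  # conditioning never inflates variance at observed years
  var_prior <- 1.5^2 + 0.1
  var_post <- apply(g$draws, 2, var)[match(obs_y, yrs)]
  expect_true(all(var_post <= var_prior * 1.15))  # Monte-Carlo slack
})

test_that("fill_time_series completes the grid, preserves flags and reruns identically", {
  cfg <- tiny_config(n_locations = 12, years = 1996:2005,
                     missing_fraction = 0.25)
  w <- generate_world(cfg)
  panel <- aggregate_availability(w$supply, w$composition, w$matching)
  params <- stgpr_params(n_draws = 200, seed = 5)
  f <- fill_time_series(panel, w$covariates, params,
                        nutrients = "energy_kcal")
  expect_equal(nrow(f), 12 * 10)
  expect_false(anyNA(f$value))
  expect_true(all(f$value >= 0 & f$lower <= f$upper))
  obs_cells <- dplyr::distinct(panel, location_id, year)
  flagged <- f[f$observed, c("location_id", "year")]
  expect_equal(dplyr::arrange(flagged, location_id, year),
               dplyr::arrange(obs_cells, location_id, year))
  expect_identical(f, fill_time_series(panel, w$covariates, params,
                                       nutrients = "energy_kcal"))

  # near-complete input with a tiny nugget: output tracks the input closely
  cfg2 <- tiny_config(n_locations = 12, years = 1996:2005,
                      missing_fraction = 0)
  w2 <- generate_world(cfg2)
  p2 <- aggregate_availability(w2$supply, w2$composition, w2$matching)
  f2 <- fill_time_series(p2, w2$covariates,
                         stgpr_params(gp_nugget = 1e-6, n_draws = 200),
                         nutrients = "energy_kcal")
  m <- dplyr::inner_join(f2, p2[p2$nutrient_id == "energy_kcal", ],
                         by = c("location_id", "year"))
  expect_lt(max(abs(m$value.x - m$value.y) / m$value.y), 1e-3)
})

test_that("smoother hyperparameters are validated", {
  expect_error(stgpr_params(lambda_time = 0), "lambda_time")
  expect_error(stgpr_params(zeta_space = 1.2), "zeta_space")
  expect_error(stgpr_params(gp_length_scale_years = -1), "length_scale")
  expect_error(stgpr_params(n_draws = 10), "n_draws")
})
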