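#' Held-out recovery experiment for the panel smoother
#'
#' Generates a synthetic world, hides the masked location-years, completes
#' the panel with the three-stage smoother, and scores it against the
#' known complete panel on the held-out cells: root-mean-square error of
#' the stage-1 covariate prior alone, RMSE of the full stage-3 posterior
#' mean, and empirical coverage of the 95% intervals.  The smoother earns
#' its keep when stage-3 beats the covariate prior and the intervals cover
#' the truth at roughly their nominal rate.
#'
#' @param config a [world_config()] with `missing_fraction > 0`
#' @param params an [stgpr_params()]
#' @param nutrient nutrient id to score (default total energy)
#' @return list: `rmse_stage1`, `rmse_stage3`, `coverage`, `n_heldout`
#' @export
heldout_recovery_experiment <- function(config,
                                        params = stgpr_params(seed = config$seed),
                                        nutrient = "energy_kcal") {
  if (config$missing_fraction <= 0) {
    stop("experiment needs missing_fraction > 0", call. = FALSE)
  }
  compo <- generate_composition_table(config)
  comp <- dplyr::select(compo$composition, -"true_carbohydrate_g",
                        -"item_class")
  sup <- generate_supply_panel(config, compo$composition)
  covs <- generate_covariates(config)
  truth <- aggregate_availability(sup$supply, comp, compo$matching) |>
    dplyr::filter(.data$nutrient_id == nutrient)
  obs_cells <- sup$mask[sup$mask$observed, c("location_id", "year")]
  obs <- dplyr::semi_join(truth, obs_cells, by = c("location_id", "year"))
  held <- dplyr::anti_join(truth, obs_cells, by = c("location_id", "year"))

  filled <- fill_time_series(obs, covs, params, nutrient)
  m3 <- dplyr::inner_join(filled, held, by = c("location_id", "year"))
  lcovs <- lag_distributed_income(covs)
  s1 <- stage1_prior(obs[, c("location_id", "year", "value")], lcovs,
                     nutrient)
  m1 <- dplyr::inner_join(s1$prior, held, by = c("location_id", "year"))
  list(rmse_stage1 = sqrt(mean((m1$prior_mean - m1$value)^2)),
       rmse_stage3 = sqrt(mean((m3$value.x - m3$value.y)^2)),
       coverage = mean(m3$value.y >= m3$lower & m3$value.y <= m3$upper),
       n_heldout = nrow(m3))
}

#' Slope-recovery simulation for the intake model
#'
#' Repeatedly simulates survey intake from a known generating slope and
#' refits the intake regression, recording whether each replicate's 95%
#' confidence interval covers the effective generating slope
#' (`true_beta * (1 - waste_factor)`: the regression is on availability,
#' so retail/household waste is absorbed into the slope).  Replicate seeds
#' derive from `root_seed` via [seed_child()].
#'
#' @param n_replicates number of simulation replicates
#' @param root_seed root seed for the replicate stream
#' @param true_beta generating slope before waste adjustment
#' @param config_args overrides for the per-replicate [world_config()]
#' @param nutrient nutrient to simulate and fit
#' @return tibble per replicate: `seed`, `beta_hat`, `se`, `ci_lo`,
#'   `ci_hi`, `effective_slope`, `covered`, `method`
#' @export
beta_recovery_experiment <- function(n_replicates = 50, root_seed = 1L,
                                     true_beta = 0.95,
                                     config_args = list(),
                                     nutrient = "protein_g") {
  defaults <- list(n_locations = 15, n_items = 20, years = 1980:2013,
                   missing_fraction = 0, waste_factor = 0.3,
                   intake_noise_frac = 0.1)
  out <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    s <- seed_child(root_seed, k)
    cfg <- do.call(world_config,
                   c(utils::modifyList(defaults, config_args),
                     list(seed = s)))
    w <- generate_world(cfg, intake_nutrients = nutrient,
                        true_beta = true_beta)
    avail <- dplyr::filter(w$ground_truth$availability_complete,
                           .data$nutrient_id == nutrient)
    by_group <- apply_age_sex_pattern(
      avail[, c("location_id", "year", "nutrient_id", "value")], w$pattern)
    srs <- dplyr::distinct(w$ground_truth$profiles, .data$location_id,
                           .data$super_region)
    rows <- dplyr::inner_join(
      w$intake, by_group,
      by = c("location_id", "year", "age_group", "sex", "nutrient_id")) |>
      dplyr::inner_join(srs, by = "location_id") |>
      dplyr::rename(availability = "value", intake = "mean_intake")
    fit <- fit_intake_model(rows)
    eff <- w$ground_truth$intake_params$effective_slope
    out[[k]] <- tibble::tibble(
      seed = s, beta_hat = fit$beta, se = fit$beta_se,
      ci_lo = fit$beta_ci[1], ci_hi = fit$beta_ci[2],
      effective_slope = eff,
      covered = fit$beta_ci[1] <= eff && eff <= fit$beta_ci[2],
      method = fit$method)
  }
  dplyr::bind_rows(out)
}
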