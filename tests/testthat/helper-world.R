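# Small worlds used across tests; kept deliberately modest so the whole
# suite runs quickly while still exercising every generator code path.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_items = 12, n_locations = 20, years = 1990:2005,
                   n_super_regions = 4, missing_fraction = 0.2, seed = 42L)
  do.call(world_config, utils::modifyList(defaults, args))
}

# one composition row, convenient for single-record operations
one_record <- function(energy = 165, protein = 10, fat = 5, alcohol = 0,
                       refuse = 0, mufa = 0, pufa = 0, sfa = fat) {
  data.frame(item_id = "x", refuse_fraction = refuse, energy_kcal = energy,
             protein_g = protein, fat_g = fat, mufa_g = mufa, pufa_g = pufa,
             sfa_g = sfa, alcohol_g = alcohol)
}

# brute-force Pearson correlation from the product-moment definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# brute-force double-loop stage-2 smoother (the independent oracle)
stage2_oracle <- function(residuals, grid, lambda_time, zeta_space) {
  years <- sort(unique(grid$year))
  dmax <- max(years) - min(years)
  out <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    num <- 0; den <- 0
    for (j in seq_len(nrow(residuals))) {
      d <- abs(grid$year[i] - residuals$year[j])
      kt <- (1 - (d / (1 + dmax))^lambda_time)^3
      ks <- if (residuals$location_id[j] == grid$location_id[i]) {
        zeta_space
      } else if (residuals$super_region[j] == grid$super_region[i]) {
        zeta_space * (1 - zeta_space)
      } else {
        (1 - zeta_space)^2
      }
      num <- num + kt * ks * residuals$resid[j]
      den <- den + kt * ks
    }
    out[i] <- num / den
  }
  out
}

# closed-form GP conditional (independent of the chol-based implementation)
gp_oracle <- function(years, prior_mean, obs_years, obs_values,
                      amplitude, length_scale, nugget) {
  k <- function(a, b) {
    r <- sqrt(3) * abs(outer(a, b, "-")) / length_scale
    amplitude^2 * (1 + r) * exp(-r)
  }
  oi <- match(obs_years, years)
  K_oo <- k(obs_years, obs_years) + diag(nugget, length(obs_years))
  K_to <- k(years, obs_years)
  prior_mean + as.vector(K_to %*% solve(K_oo, obs_values - prior_mean[oi]))
}
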