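#' Hyperparameters for the three-stage spatiotemporal smoother
#'
#' Stage 1 is a covariate regression prior (nutrient value on log
#' lag-distributed income with super-region intercepts), stage 2 smooths
#' stage-1 residuals over space and time with separable kernel weights, and
#' stage 3 conditions an independent per-location Gaussian process over
#' years on the observed data, with the stage-1+2 surface as prior mean.
#'
#' @param lambda_time time-kernel decay exponent (> 0); larger values
#'   concentrate weight on nearby years
#' @param zeta_space spatial borrowing weight in \[0, 1\]: weight `zeta` for
#'   the location's own data, `zeta (1 - zeta)` for its super-region,
#'   `(1 - zeta)^2` elsewhere
#' @param gp_amplitude GP marginal SD; `NULL` (default) uses the SD of the
#'   stage-1 residuals
#' @param gp_length_scale_years Matern-3/2 length scale in years (> 0)
#' @param gp_nugget observation noise variance; `NULL` (default) uses the
#'   mean squared deviation of observed residuals from the stage-2 surface
#' @param nugget_floor lower bound applied to the nugget so the observed
#'   covariance stays positive definite
#' @param n_draws number of posterior draws for uncertainty intervals
#'   (>= 100)
#' @param seed integer seed for the draws
#' @return a validated `stgpr_params` list
#' @export
stgpr_params <- function(lambda_time = 0.5, zeta_space = 0.9,
                         gp_amplitude = NULL, gp_length_scale_years = 10,
                         gp_nugget = NULL, nugget_floor = 1e-8,
                         n_draws = 1000, seed = 1L) {
  if (lambda_time <= 0) abort_field("lambda_time", "must be > 0")
  if (zeta_space < 0 || zeta_space > 1) {
    abort_field("zeta_space", "must lie in [0, 1]")
  }
  if (gp_length_scale_years <= 0) {
    abort_field("gp_length_scale_years", "must be > 0")
  }
  if (!is.null(gp_nugget) && gp_nugget < 0) {
    abort_field("gp_nugget", "must be >= 0")
  }
  if (n_draws < 100) abort_field("n_draws", "must be >= 100")
  structure(list(lambda_time = lambda_time, zeta_space = zeta_space,
                 gp_amplitude = gp_amplitude,
                 gp_length_scale_years = gp_length_scale_years,
                 gp_nugget = gp_nugget, nugget_floor = nugget_floor,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "stgpr_params")
}

#' Lag-distributed income covariate
#'
#' Weighted average of income per capita over the current and previous
#' `window - 1` years, with linearly decaying weights (most recent year
#' heaviest; default `(10, 9, ..., 1) / 55`).  Early years with a shorter
#' history renormalise the weights over the years available, so a constant
#' income series maps to itself everywhere.
#'
#' @param covariates tibble with `location_id`, `year`, `income_per_capita`
#' @param window lag window length in years (default 10)
#' @param weights optional weight vector of length `window`, most recent
#'   first; normalised internally
#' @return the covariate tibble with an added `ldi` column
#' @export
lag_distributed_income <- function(covariates, window = 10, weights = NULL) {
  if (nrow(covariates) == 0) stop("empty income series", call. = FALSE)
  if (any(covariates$income_per_capita <= 0)) {
    stop("income must be strictly positive", call. = FALSE)
  }
  if (is.null(weights)) weights <- seq(window, 1)
  if (length(weights) != window) {
    stop("weights must have length `window`", call. = FALSE)
  }
  covariates |>
    dplyr::group_by(.data$location_id) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(ldi = {
      x <- .data$income_per_capita
      n <- length(x)
      out <- numeric(n)
      for (t in seq_len(n)) {
        k <- seq_len(min(window, t))        # lags 0 .. min(window,t)-1
        w <- weights[k]
        out[t] <- sum(w * x[t - k + 1]) / sum(w)
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Stage 1: covariate regression prior
#'
#' Linear regression of the observed nutrient values on log lag-distributed
#' income with super-region intercepts, evaluated at every location-year of
#' the covariate grid — including locations with no observations at all,
#' which receive their super-region's regression line (or, for a
#' super-region never observed, the average super-region line).
#'
#' @param observed tibble of observed cells: `location_id`, `year`, `value`
#' @param covariates tibble with `location_id`, `year`, `ldi`,
#'   `super_region` (see [lag_distributed_income()])
#' @param nutrient_id label used in error messages
#' @return list with `prior` (covariate grid plus `prior_mean`), `fit`
#'   (the `lm` object) and `residuals` (observed cells with `resid`)
#' @export
stage1_prior <- function(observed, covariates, nutrient_id = "nutrient") {
  if (nrow(observed) < 2) {
    stop("all observations missing for ", nutrient_id,
         ": cannot fit stage-1 prior", call. = FALSE)
  }
  dat <- observed |>
    dplyr::inner_join(covariates[, c("location_id", "year", "ldi",
                                     "super_region")],
                      by = c("location_id", "year"))
  dat$log_ldi <- log(dat$ldi)
  n_sr <- length(unique(dat$super_region))
  fit <- if (n_sr > 1) {
    lm(value ~ log_ldi + super_region, data = dat)
  } else {
    lm(value ~ log_ldi, data = dat)
  }
  cf <- coef(fit)
  slope <- cf[["log_ldi"]]
  sr_seen <- sort(unique(dat$super_region))
  offsets <- setNames(rep(0, length(sr_seen)), sr_seen)
  for (s in sr_seen[-1]) {
    nm <- paste0("super_region", s)
    if (nm %in% names(cf)) offsets[[s]] <- cf[[nm]]
  }
  grid <- covariates[, c("location_id", "year", "ldi", "super_region")]
  off <- offsets[grid$super_region]
  off[is.na(off)] <- mean(offsets)          # super-region never observed
  grid$prior_mean <- cf[["(Intercept)"]] + slope * log(grid$ldi) + off
  resids <- dat
  resids$resid <- dat$value - predict(fit, dat)
  list(prior = tibble::as_tibble(grid), fit = fit,
       residuals = tibble::as_tibble(
         resids[, c("location_id", "year", "super_region", "resid")]))
}

# Time kernel on absolute year distance: (1 - (d / (1 + dmax))^lambda)^3.
# Strictly positive for d <= dmax, so stage-2 weights always normalise.
st_time_kernel <- function(d, dmax, lambda_time) {
  (1 - (d / (1 + dmax))^lambda_time)^3
}

#' Stage 2: spatiotemporal residual smoothing
#'
#' Every location-year receives a weighted average of all observed stage-1
#' residuals.  The weight of an observed residual at time distance `d` is
#' the time kernel `(1 - (d / (1 + dmax))^lambda_time)^3` times a spatial
#' tier weight: `zeta` if it comes from the same location, `zeta (1 - zeta)`
#' from another location in the same super-region, `(1 - zeta)^2`
#' otherwise; weights are normalised to sum to 1 per target cell.
#'
#' Implemented by aggregating residual sums per (location, year),
#' (super-region, year) and year, then applying the year-by-year kernel
#' matrix — algebraically identical to the direct double loop over cells.
#'
#' @param residuals observed cells with `location_id`, `year`,
#'   `super_region`, `resid`
#' @param grid target cells: `location_id`, `year`, `super_region`
#' @param lambda_time,zeta_space kernel hyperparameters (see
#'   [stgpr_params()])
#' @return the grid with an added `smooth_resid` column
#' @export
stage2_residual_smooth <- function(residuals, grid, lambda_time = 0.5,
                                   zeta_space = 0.9) {
  if (nrow(residuals) == 0) {
    stop("no observed residuals to smooth", call. = FALSE)
  }
  years <- sort(unique(grid$year))
  locs <- unique(grid$location_id)
  dmax <- max(years) - min(years)
  K <- st_time_kernel(abs(outer(years, years, "-")), dmax, lambda_time)

  yi <- match(residuals$year, years)
  li <- match(residuals$location_id, locs)
  sr_levels <- sort(unique(grid$super_region))

  S_loc <- matrix(0, length(locs), length(years))
  N_loc <- matrix(0, length(locs), length(years))
  S_loc[cbind(li, yi)] <- S_loc[cbind(li, yi)] + residuals$resid
  N_loc[cbind(li, yi)] <- N_loc[cbind(li, yi)] + 1
  loc_sr <- grid$super_region[match(locs, grid$location_id)]
  S_sr <- rowsum(S_loc, loc_sr)   # rows ordered by sorted super-region
  N_sr <- rowsum(N_loc, loc_sr)
  s_all <- colSums(S_loc)
  n_all <- colSums(N_loc)

  A_loc <- S_loc %*% K;  B_loc <- N_loc %*% K
  A_sr <- S_sr %*% K;    B_sr <- N_sr %*% K
  a_all <- as.vector(s_all %*% K)
  b_all <- as.vector(n_all %*% K)

  z <- zeta_space
  w1 <- z; w2 <- z * (1 - z); w3 <- (1 - z)^2
  gl <- match(grid$location_id, locs)
  gy <- match(grid$year, years)
  gs <- match(grid$super_region, sr_levels)
  num <- w1 * A_loc[cbind(gl, gy)] +
    w2 * (A_sr[cbind(gs, gy)] - A_loc[cbind(gl, gy)]) +
    w3 * (a_all[gy] - A_sr[cbind(gs, gy)])
  den <- w1 * B_loc[cbind(gl, gy)] +
    w2 * (B_sr[cbind(gs, gy)] - B_loc[cbind(gl, gy)]) +
    w3 * (b_all[gy] - B_sr[cbind(gs, gy)])
  out <- grid
  out$smooth_resid <- num / den
  tibble::as_tibble(out)
}

# Matern-3/2 covariance on year distance.
matern32 <- function(d, amplitude, length_scale) {
  r <- sqrt(3) * d / length_scale
  amplitude^2 * (1 + r) * exp(-r)
}

#' Stage 3: per-location Gaussian-process posterior
#'
#' For one location, a GP over years with Matern-3/2 covariance and the
#' stage-1+2 surface as prior mean is conditioned on the observed values
#' (observation noise = nugget).  Returns the posterior mean, a 95%
#' interval from seeded predictive draws (posterior draws plus observation
#' noise), and the draws themselves.  With no observations the prior mean
#' and prior variance are returned unchanged.
#'
#' @param years integer vector of target years (sorted)
#' @param prior_mean prior mean at each target year
#' @param obs_years,obs_values observed years (subset of `years`) and values
#' @param params an [stgpr_params()] with `gp_amplitude` and `gp_nugget` set
#' @param draw_seed integer seed for the draws
#' @return list with `mean`, `lower`, `upper`, `draws` (matrix
#'   `n_draws x length(years)`)
#' @export
stage3_gp <- function(years, prior_mean, obs_years, obs_values, params,
                      draw_seed = params$seed) {
  amp <- params$gp_amplitude
  nug <- max(params$gp_nugget, params$nugget_floor)
  ell <- params$gp_length_scale_years
  n <- length(years)
  K_tt <- matern32(abs(outer(years, years, "-")), amp, ell)
  if (length(obs_years) == 0) {
    post_mean <- prior_mean
    post_cov <- K_tt
  } else {
    oi <- match(obs_years, years)
    if (anyNA(oi)) stop("observed years outside target grid", call. = FALSE)
    K_oo <- K_tt[oi, oi, drop = FALSE] + diag(nug, length(oi))
    K_to <- K_tt[, oi, drop = FALSE]
    ch <- tryCatch(chol(K_oo), error = function(e) {
      stop("observation covariance not positive definite; ",
           "increase the nugget floor", call. = FALSE)
    })
    alpha <- backsolve(ch, forwardsolve(t(ch), obs_values - prior_mean[oi]))
    post_mean <- prior_mean + as.vector(K_to %*% alpha)
    V <- forwardsolve(t(ch), t(K_to))
    post_cov <- K_tt - crossprod(V)
  }
  # predictive draws: posterior of the latent series plus observation noise
  set.seed(draw_seed)
  ch_p <- chol(post_cov + diag(params$nugget_floor, n))
  z <- matrix(rnorm(params$n_draws * n), params$n_draws, n)
  draws <- matrix(post_mean, params$n_draws, n, byrow = TRUE) + z %*% ch_p +
    matrix(rnorm(params$n_draws * n, 0, sqrt(nug)), params$n_draws, n)
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  list(mean = post_mean, lower = qs[1, ], upper = qs[2, ], draws = draws)
}

#' Complete a sparse availability panel with uncertainty intervals
#'
#' Runs the three stages for each nutrient in the panel: covariate prior,
#' spatiotemporal residual smoothing, and per-location GP conditioning.
#' Every (nutrient, location, year) cell of the covariate grid is
#' populated; filled values and interval bounds are floored at 0
#' (availability cannot be negative) and the observed flag is preserved.
#'
#' @param panel long availability panel of observed cells (`location_id`,
#'   `year`, `nutrient_id`, `value`; see [aggregate_availability()])
#' @param covariates covariate tibble covering the full location-year grid
#'   (`location_id`, `year`, `income_per_capita`, `super_region`)
#' @param params an [stgpr_params()]; `gp_amplitude`/`gp_nugget` left
#'   `NULL` are estimated from the residuals per nutrient
#' @param nutrients nutrient ids to fill (default: all in the panel)
#' @return long tibble `location_id`, `year`, `nutrient_id`, `value`,
#'   `unit`, `lower`, `upper`, `observed`
#' @export
fill_time_series <- function(panel, covariates, params = stgpr_params(),
                             nutrients = unique(panel$nutrient_id)) {
  covs <- lag_distributed_income(covariates)
  grid <- covs[, c("location_id", "year", "super_region")]
  out <- vector("list", length(nutrients))
  for (i in seq_along(nutrients)) {
    nut <- nutrients[i]
    obs <- panel[panel$nutrient_id == nut,
                 c("location_id", "year", "value")]
    s1 <- stage1_prior(obs, covs, nutrient_id = nut)
    s2 <- stage2_residual_smooth(s1$residuals, grid,
                                 params$lambda_time, params$zeta_space)
    prior <- dplyr::inner_join(
      s1$prior[, c("location_id", "year", "prior_mean")],
      s2[, c("location_id", "year", "smooth_resid")],
      by = c("location_id", "year"))
    prior$prior_mean <- prior$prior_mean + prior$smooth_resid

    p <- params
    if (is.null(p$gp_amplitude)) p$gp_amplitude <- sd(s1$residuals$resid)
    if (is.null(p$gp_nugget)) {
      at_obs <- dplyr::inner_join(
        s1$residuals, s2[, c("location_id", "year", "smooth_resid")],
        by = c("location_id", "year"))
      p$gp_nugget <- mean((at_obs$resid - at_obs$smooth_resid)^2)
    }
    years <- sort(unique(grid$year))
    locs <- unique(grid$location_id)
    res <- vector("list", length(locs))
    for (j in seq_along(locs)) {
      l <- locs[j]
      pr <- prior[prior$location_id == l, ]
      pr <- pr[order(pr$year), ]
      ol <- obs[obs$location_id == l, ]
      g <- stage3_gp(pr$year, pr$prior_mean, ol$year, ol$value, p,
                     draw_seed = seed_child(p$seed, 100 * i + j))
      res[[j]] <- tibble::tibble(location_id = l, year = pr$year,
                                 nutrient_id = nut,
                                 value = pmax(0, g$mean),
                                 lower = pmax(0, g$lower),
                                 upper = pmax(0, g$upper))
    }
    filled <- dplyr::bind_rows(res)
    obs$observed <- TRUE
    filled <- dplyr::left_join(filled, obs[, c("location_id", "year",
                                               "observed")],
                               by = c("location_id", "year"))
    filled$observed[is.na(filled$observed)] <- FALSE
    filled$unit <- nutrient_unit(nut)
    out[[i]] <- filled
  }
  dplyr::bind_rows(out)[, c("location_id", "year", "nutrient_id", "value",
                            "unit", "lower", "upper", "observed")]
}
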