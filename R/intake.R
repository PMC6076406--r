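#' Split national availability across age/sex groups
#'
#' Applies an age/sex intake pattern to national availability values and
#' renormalises the multipliers so that the population-weighted mean over
#' groups equals the national value exactly: the pattern redistributes, it
#' never creates or destroys nutrient mass.
#'
#' @param availability tibble `location_id`, `year`, `nutrient_id`, `value`
#' @param pattern tibble `age_group`, `sex`, `multiplier` (> 0), `weight`
#'   (population weights, summing to 1 after normalisation)
#' @param groups optional tibble `age_group`, `sex` enumerating the groups
#'   that must be covered; an uncovered group is a schema error
#' @return tibble with one row per availability row per group:
#'   `location_id`, `year`, `age_group`, `sex`, `nutrient_id`, `value`
#' @export
apply_age_sex_pattern <- function(availability, pattern, groups = NULL) {
  need <- c("age_group", "sex", "multiplier", "weight")
  if (!all(need %in% names(pattern))) {
    stop("pattern must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(pattern$multiplier <= 0)) {
    stop("pattern multipliers must be positive", call. = FALSE)
  }
  if (!is.null(groups)) {
    have <- paste(pattern$age_group, pattern$sex)
    want <- paste(groups$age_group, groups$sex)
    miss <- setdiff(want, have)
    if (length(miss)) {
      stop("pattern missing group(s): ", paste(miss, collapse = "; "),
           call. = FALSE)
    }
  }
  pat <- pattern
  pat$weight <- pat$weight / sum(pat$weight)
  pat$multiplier <- pat$multiplier / sum(pat$multiplier * pat$weight)
  out <- tidyr::crossing(availability,
                         pat[, c("age_group", "sex", "multiplier")])
  out$value <- out$value * out$multiplier
  dplyr::select(out, "location_id", "year", "age_group", "sex",
                "nutrient_id", "value")
}

#' Fit the intake-from-availability regression
#'
#' Linear model of survey mean intake on age/sex-specific availability with
#' age, sex and super-region intercepts:
#' `intake = beta * availability + age + sex + alpha_super_region`.
#' The super-region term is a random (exchangeable) intercept fitted by
#' `lme4::lmer`; when fewer than three super-regions are present or the
#' mixed fit is singular, a fixed-effects fallback (`lm` with super-region
#' dummies) is used and reported.
#'
#' @param rows matched tibble with columns `intake`, `availability`,
#'   `age_group`, `sex`, `super_region`
#' @return object of class `intake_model_fit`: `beta`, `beta_se`,
#'   `beta_ci` (95% Wald), `residual_sd`, `method`
#'   (`"mixed"`/`"fixed"`), `diagnostics` (captured optimizer notes), and
#'   the underlying `fit`
#' @export
fit_intake_model <- function(rows) {
  need <- c("intake", "availability", "age_group", "sex", "super_region")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("rows lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(rows) < 30) stop("need >= 30 rows", call. = FALSE)
  n_sr <- length(unique(rows$super_region))
  if (n_sr < 2) stop("need >= 2 super-regions", call. = FALSE)
  rows <- dplyr::mutate(rows,
                        age_group = factor(.data$age_group),
                        sex = factor(.data$sex),
                        super_region = factor(.data$super_region))
  # collinearity check on the fixed part
  X <- stats::model.matrix(~ availability + age_group + sex, data = rows)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  method <- "mixed"
  fit <- NULL
  diagnostics <- character()
  if (n_sr >= 3) {
    fit <- withCallingHandlers(
      tryCatch(
        lme4::lmer(intake ~ availability + age_group + sex +
                     (1 | super_region), data = rows, REML = TRUE),
        error = function(e) NULL),
      warning = function(w) {
        diagnostics <<- c(diagnostics, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (!is.null(fit) && lme4::isSingular(fit, tol = 1e-5)) fit <- NULL
  }
  if (is.null(fit)) {
    method <- "fixed"
    fit <- lm(intake ~ availability + age_group + sex + super_region,
              data = rows)
  }
  if (method == "mixed") {
    sm <- summary(fit)$coefficients
    beta <- sm["availability", "Estimate"]
    se <- sm["availability", "Std. Error"]
    resid_sd <- stats::sigma(fit)
  } else {
    sm <- summary(fit)$coefficients
    beta <- sm["availability", "Estimate"]
    se <- sm["availability", "Std. Error"]
    resid_sd <- stats::sigma(fit)
  }
  if (!all(is.finite(c(beta, se)))) {
    stop("non-finite coefficient estimates", call. = FALSE)
  }
  structure(list(beta = beta, beta_se = se,
                 beta_ci = beta + c(-1, 1) * qt(0.975, stats::df.residual(fit)) * se,
                 residual_sd = resid_sd, method = method, fit = fit,
                 diagnostics = diagnostics,
                 levels = list(age_group = levels(rows$age_group),
                               sex = levels(rows$sex),
                               super_region = levels(rows$super_region))),
            class = "intake_model_fit")
}

#' @export
print.intake_model_fit <- function(x, ...) {
  cat(sprintf("intake model (%s effects): beta = %.4f (SE %.4f, 95%% CI %.4f-%.4f), residual SD %.3f\n",
              x$method, x$beta, x$beta_se, x$beta_ci[1], x$beta_ci[2],
              x$residual_sd))
  invisible(x)
}

#' @export
predict.intake_model_fit <- function(object, newdata, ...) {
  newdata <- dplyr::mutate(
    newdata,
    age_group = factor(.data$age_group, levels = object$levels$age_group),
    sex = factor(.data$sex, levels = object$levels$sex),
    super_region = factor(.data$super_region,
                          levels = object$levels$super_region))
  if (object$method == "mixed") {
    predict(object$fit, newdata = newdata, allow.new.levels = TRUE)
  } else {
    predict(object$fit, newdata = newdata)
  }
}

# --- regressor registry -----------------------------------------------------
# Any model with a fit(rows) -> object and predict(object, rows) -> numeric
# contract can be evaluated out of sample; tree ensembles register here.

.regressors <- new.env(parent = emptyenv())

#' Register a regressor for out-of-sample evaluation
#'
#' @param name registry key
#' @param fit function(rows) returning a fitted object; rows carry
#'   `intake`, `availability`, `age_group`, `sex`, `super_region`
#' @param predict function(object, rows) returning predicted intake
#' @return the name, invisibly
#' @export
register_regressor <- function(name, fit, predict) {
  stopifnot(is.function(fit), is.function(predict))
  assign(name, list(fit = fit, predict = predict), envir = .regressors)
  invisible(name)
}

#' List registered regressors
#' @return character vector of registry keys
#' @export
list_regressors <- function() sort(ls(.regressors))

get_regressor <- function(name) {
  if (!exists(name, envir = .regressors, inherits = FALSE)) {
    stop("unknown regressor '", name, "'; registered: ",
         paste(list_regressors(), collapse = ", "), call. = FALSE)
  }
  get(name, envir = .regressors, inherits = FALSE)
}

regressor_frame <- function(rows) {
  data.frame(availability = rows$availability,
             age_group = factor(rows$age_group),
             sex = factor(rows$sex),
             super_region = factor(rows$super_region))
}

register_builtin_regressors <- function() {
  register_regressor(
    "linear",
    fit = fit_intake_model,
    predict = function(object, rows) predict(object, rows))
  if (requireNamespace("ranger", quietly = TRUE)) {
    register_regressor(
      "random_forest",
      fit = function(rows) {
        df <- regressor_frame(rows); df$intake <- rows$intake
        ranger::ranger(intake ~ ., data = df, num.trees = 300, seed = 1)
      },
      predict = function(object, rows) {
        predict(object, data = regressor_frame(rows))$predictions
      })
  }
  if (requireNamespace("xgboost", quietly = TRUE)) {
    to_mat <- function(rows) {
      stats::model.matrix(~ availability + age_group + sex + super_region,
                          data = regressor_frame(rows))
    }
    register_regressor(
      "xgboost",
      fit = function(rows) {
        xgboost::xgboost(x = to_mat(rows), y = rows$intake,
                         nrounds = 150, max_depth = 4, learning_rate = 0.1,
                         verbosity = 0, nthreads = 1)
      },
      predict = function(object, rows) {
        predict(object, newdata = to_mat(rows))
      })
  }
}

#' Out-of-sample evaluation of an intake regressor
#'
#' Splits the matched rows into training and held-out folds, fits the
#' requested regressor on the training fold, and reports root mean-square
#' error and Pearson correlation on the held-out fold.  The default scheme
#' holds out whole locations, matching the use case of predicting intake
#' for places with no survey.
#'
#' @param rows matched tibble (see [fit_intake_model()]) with a
#'   `location_id` column
#' @param regressor registry key (see [list_regressors()])
#' @param scheme `"by-location"`, `"by-year"` or `"random"`
#' @param holdout_fraction fraction of units held out
#' @param seed integer seed controlling the split
#' @return list with `rmse`, `r` (`NA` with `r_defined = FALSE` when the
#'   predictions are constant), `n_train`, `n_test`
#' @export
evaluate_out_of_sample <- function(rows, regressor = "linear",
                                   scheme = c("by-location", "by-year",
                                              "random"),
                                   holdout_fraction = 0.2, seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(as.integer(seed))
  unit <- switch(scheme,
                 "by-location" = rows$location_id,
                 "by-year" = rows$year,
                 "random" = seq_len(nrow(rows)))
  units <- unique(unit)
  n_hold <- max(1, round(holdout_fraction * length(units)))
  held <- sample(units, n_hold)
  test_idx <- unit %in% held
  if (!any(test_idx) || all(test_idx)) {
    stop("degenerate holdout split", call. = FALSE)
  }
  reg <- get_regressor(regressor)
  model <- reg$fit(rows[!test_idx, ])
  pred <- reg$predict(model, rows[test_idx, ])
  obs <- rows$intake[test_idx]
  rmse <- sqrt(mean((pred - obs)^2))
  r_defined <- sd(pred) > 0 && sd(obs) > 0
  list(rmse = rmse,
       r = if (r_defined) cor(pred, obs) else NA_real_,
       r_defined = r_defined,
       n_train = sum(!test_idx), n_test = sum(test_idx))
}

#' Compare macronutrient energy shares between availability and intake
#'
#' Availability exceeds consumption because of retail and household waste,
#' but a uniform waste factor cancels out of energy *shares*; comparing
#' shares is therefore the waste-invariant validation of the accounting
#' against surveys.  Both sources are reduced to percent of Atwater energy
#' over the macronutrients present in both, and absolute share differences
#' in percentage points are reported per location-year.
#'
#' @param panel availability panel with macronutrient mass entries
#'   (`protein_g`, `carbohydrate_g`, `fat_g`, optionally `alcohol_g`)
#' @param intake intake tibble `location_id`, `year`, `age_group`, `sex`,
#'   `nutrient_id`, `mean_intake` (macronutrient masses, g)
#' @param weights optional group weights (`age_group`, `sex`, `weight`);
#'   default equal weights
#' @return tibble `location_id`, `year`, `nutrient`, `share_avail`,
#'   `share_intake`, `diff_points`
#' @export
compare_energy_shares <- function(panel, intake, weights = NULL) {
  macros_all <- c(protein_g = "protein", carbohydrate_g = "carbohydrate",
                  fat_g = "fat", alcohol_g = "alcohol")
  have <- intersect(names(macros_all),
                    intersect(unique(panel$nutrient_id),
                              unique(intake$nutrient_id)))
  if (length(have) < 2) {
    stop("need at least two shared macronutrient mass series", call. = FALSE)
  }
  kcal_per_g <- setNames(ATWATER[macros_all[have]], have)

  if (is.null(weights)) {
    grp <- dplyr::distinct(intake, .data$age_group, .data$sex)
    weights <- dplyr::mutate(grp, weight = 1 / dplyr::n())
  }
  nat_intake <- intake |>
    dplyr::filter(.data$nutrient_id %in% have) |>
    dplyr::inner_join(weights, by = c("age_group", "sex")) |>
    dplyr::group_by(.data$location_id, .data$year, .data$nutrient_id) |>
    dplyr::summarise(value = sum(.data$mean_intake * .data$weight) /
                       sum(.data$weight), .groups = "drop")

  share_of <- function(df) {
    wide <- tidyr::pivot_wider(df, names_from = "nutrient_id",
                               values_from = "value")
    kc <- sapply(have, function(h) kcal_per_g[[h]] * wide[[h]])
    kc <- matrix(kc, nrow = nrow(wide))
    total <- rowSums(kc)
    keep <- total > 0
    if (!all(keep)) warning("zero-energy cell(s) skipped", call. = FALSE)
    out <- tibble::tibble(location_id = rep(wide$location_id[keep],
                                            length(have)),
                          year = rep(wide$year[keep], length(have)),
                          nutrient = rep(unname(macros_all[have]),
                                         each = sum(keep)),
                          share = 100 * as.vector(kc[keep, , drop = FALSE]) /
                            rep(total[keep], length(have)))
    out
  }
  av <- share_of(panel |>
                   dplyr::filter(.data$nutrient_id %in% have) |>
                   dplyr::select("location_id", "year", "nutrient_id",
                                 "value"))
  iv <- share_of(nat_intake)
  dplyr::inner_join(av, iv, by = c("location_id", "year", "nutrient"),
                    suffix = c("_avail", "_intake")) |>
    dplyr::mutate(diff_points = abs(.data$share_avail - .data$share_intake))
}
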