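#' @importFrom rlang .data
#' @importFrom stats rnorm runif rbinom rgamma quantile sd var coef lm predict
#'   qt pt setNames cor rlnorm
#' @importFrom utils write.csv read.csv
NULL

# Atwater metabolizable-energy factors (kcal per g)
ATWATER <- c(protein = 4, carbohydrate = 4, fat = 9, alcohol = 7)

#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from a single root seed.  Child
#' streams (composition, supply, covariates, intake, draws, ...) use
#' `seed_child(root, k)` with a documented stream index `k`, so that every
#' generator is individually reproducible and streams do not collide.
#' The rule is `(root * 1009 + k) mod (2^31 - 1)`, kept inside the 32-bit
#' integer range R requires of `set.seed()`.
#'
#' @param root integer root seed
#' @param stream small non-negative integer stream index
#' @return an integer seed
#' @export
seed_child <- function(root, stream) {
  as.integer((as.numeric(root) * 1009 + stream) %% (2^31 - 1))
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

stopifnot_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
}

#' Round energy for reporting (nearest 5 kcal)
#'
#' Reporting convention only; internal values are kept at full precision.
#' @param kcal numeric vector of energies
#' @return numeric vector rounded to the nearest 5 kcal
#' @export
report_kcal <- function(kcal) 5 * round(kcal / 5)

#' Round an energy share for reporting (one decimal, percent)
#' @param share_pct numeric vector of shares in percent
#' @return numeric vector rounded to 1 decimal place
#' @export
report_share <- function(share_pct) round(share_pct, 1)

# Check that two panel entries / series carry the same unit before arithmetic.
check_same_unit <- function(unit_a, unit_b, context = "arithmetic") {
  ua <- unique(unit_a)
  ub <- unique(unit_b)
  if (length(ua) != 1L || length(ub) != 1L || !identical(ua, ub)) {
    stop(sprintf("unit mismatch in %s: '%s' vs '%s'", context,
                 paste(ua, collapse = ","), paste(ub, collapse = ",")),
         call. = FALSE)
  }
  invisible(ua)
}
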