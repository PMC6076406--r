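#' Edible mass after refuse removal
#'
#' Food supply figures refer to gross commodity weight; the inedible
#' proportion (bones, peel, shells — the refuse factor) must be removed
#' before any nutrient calculation.  Refuse factors are treated as constant
#' across countries and years, so this is a pure scalar adjustment.
#'
#' @param gross_g_per_person_day gross availability, g/person/day (>= 0)
#' @param refuse_fraction inedible proportion in \[0, 1\]
#' @return edible mass rate, g/person/day
#' @examples
#' edible_fraction_mass(100, 0.3)  # 70
#' @export
edible_fraction_mass <- function(gross_g_per_person_day, refuse_fraction) {
  if (any(!is.finite(refuse_fraction)) ||
      any(refuse_fraction < 0) || any(refuse_fraction > 1)) {
    stop("refuse_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(gross_g_per_person_day < 0)) {
    stop("gross mass must be non-negative", call. = FALSE)
  }
  gross_g_per_person_day * (1 - refuse_fraction)
}

#' Atwater metabolizable energy
#'
#' Energy per 100 g edible portion using the Atwater general factors:
#' 4 kcal/g protein, 4 kcal/g carbohydrate, 9 kcal/g fat, 7 kcal/g alcohol.
#'
#' @param protein_g,carbohydrate_g,fat_g,alcohol_g grams per 100 g edible
#'   portion (all >= 0); vectors recycle in the usual way
#' @return energy in kcal per 100 g
#' @examples
#' atwater_energy(10, 20, 5, 0)  # 165
#' @export
atwater_energy <- function(protein_g, carbohydrate_g, fat_g, alcohol_g = 0) {
  if (any(protein_g < 0) || any(carbohydrate_g < 0) ||
      any(fat_g < 0) || any(alcohol_g < 0)) {
    stop("macronutrient masses must be non-negative", call. = FALSE)
  }
  ATWATER[["protein"]] * protein_g + ATWATER[["carbohydrate"]] * carbohydrate_g +
    ATWATER[["fat"]] * fat_g + ATWATER[["alcohol"]] * alcohol_g
}

#' Validate a composition record (or table of records)
#'
#' Checks the invariants a composition row must satisfy before
#' carbohydrate-by-difference is meaningful: refuse in \[0,1\], non-negative
#' densities, fat subtypes not exceeding total fat, and stored energy at
#' least the energy from protein, fat and alcohol.
#'
#' @param record data frame with columns `item_id`, `refuse_fraction`,
#'   `energy_kcal`, `protein_g`, `fat_g`, `mufa_g`, `pufa_g`, `sfa_g`,
#'   `alcohol_g`
#' @param tol numeric slack for the fat-subtype and energy inequalities
#' @return the record, invisibly; warns on fat subtypes exceeding total fat,
#'   errors on hard invariant violations
#' @export
validate_composition <- function(record, tol = 1e-6) {
  need <- c("item_id", "refuse_fraction", "energy_kcal", "protein_g",
            "fat_g", "mufa_g", "pufa_g", "sfa_g", "alcohol_g")
  missing_cols <- setdiff(need, names(record))
  if (length(missing_cols)) {
    stop("composition table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(record$refuse_fraction < 0 | record$refuse_fraction > 1)) {
    stop("refuse_fraction outside [0, 1] for item(s): ",
         paste(record$item_id[record$refuse_fraction < 0 |
                                record$refuse_fraction > 1], collapse = ", "),
         call. = FALSE)
  }
  dens <- c("energy_kcal", "protein_g", "fat_g", "mufa_g", "pufa_g",
            "sfa_g", "alcohol_g")
  for (col in dens) {
    if (any(record[[col]] < 0)) {
      stop(sprintf("negative %s for item(s): %s", col,
                   paste(record$item_id[record[[col]] < 0], collapse = ", ")),
           call. = FALSE)
    }
  }
  subtype_excess <- record$mufa_g + record$pufa_g + record$sfa_g >
    record$fat_g + tol
  if (any(subtype_excess)) {
    warning("fat subtypes exceed total fat for item(s): ",
            paste(record$item_id[subtype_excess], collapse = ", "),
            "; total fat governs energy", call. = FALSE)
  }
  invisible(record)
}

#' Digestible carbohydrate by difference
#'
#' Carbohydrate is inferred from the gap between a food's stored total
#' energy and the energy accounted for by protein, fat and alcohol under
#' the Atwater factors: `(energy - 4 P - 9 F - 7 A) / 4`.  This excludes
#' indigestible dietary fibre, which contributes no metabolizable energy,
#' so the result is monosaccharides, disaccharides and starches only.
#' Real composition tables occasionally carry an energy field slightly
#' below the protein+fat+alcohol energy; the negative difference is clamped
#' to zero with a warning, since negative digestible carbohydrate is not
#' meaningful.
#'
#' @param record composition data frame (see [validate_composition()])
#' @return numeric vector, g digestible carbohydrate per 100 g edible portion
#' @examples
#' rec <- data.frame(item_id = "x", refuse_fraction = 0, energy_kcal = 165,
#'                   protein_g = 10, fat_g = 5, mufa_g = 0, pufa_g = 0,
#'                   sfa_g = 0, alcohol_g = 0)
#' carbohydrate_by_difference(rec)  # 20
#' @export
carbohydrate_by_difference <- function(record) {
  validate_composition(record)
  carb <- (record$energy_kcal -
             ATWATER[["protein"]] * record$protein_g -
             ATWATER[["fat"]] * record$fat_g -
             ATWATER[["alcohol"]] * record$alcohol_g) / ATWATER[["carbohydrate"]]
  neg <- carb < 0
  if (any(neg)) {
    warning("negative carbohydrate-by-difference clamped to 0 for item(s): ",
            paste(record$item_id[neg], collapse = ", "), call. = FALSE)
    carb[neg] <- 0
  }
  carb
}

#' Validate a supply-to-composition matching table
#'
#' The matching table links each supply item to a composition record.  The
#' report lists supply items with no match, matches pointing at composition
#' records that do not exist, and — when two independent coder columns are
#' present — rows where the coders disagreed.  The pipeline refuses to
#' proceed with unmatched items unless they are on an explicit allow-list.
#'
#' @param match data frame with columns `supply_item_id`,
#'   `composition_item_id` and optionally `coder_a`, `coder_b`
#' @param supply_items character/integer vector of item ids present in the
#'   supply data
#' @param composition_table composition data frame with `item_id`
#' @param allow_unmatched item ids allowed to stay unmatched
#' @return a list of class `nutledger_match_report` with elements
#'   `unmatched`, `dangling`, `disagreements`, `duplicated_supply_ids`, `ok`
#' @export
validate_matching <- function(match, supply_items, composition_table,
                              allow_unmatched = character()) {
  unmatched <- setdiff(as.character(supply_items),
                       as.character(match$supply_item_id))
  unmatched <- setdiff(unmatched, as.character(allow_unmatched))
  dangling <- setdiff(as.character(match$composition_item_id),
                      as.character(composition_table$item_id))
  dup <- unique(match$supply_item_id[duplicated(match$supply_item_id)])
  disagreements <- character()
  if (all(c("coder_a", "coder_b") %in% names(match))) {
    both <- !is.na(match$coder_a) & !is.na(match$coder_b)
    dis <- both & match$coder_a != match$coder_b
    disagreements <- as.character(match$supply_item_id[dis])
  }
  report <- structure(
    list(unmatched = unmatched, dangling = dangling,
         disagreements = disagreements,
         duplicated_supply_ids = as.character(dup),
         ok = length(unmatched) == 0 && length(dangling) == 0 &&
           length(dup) == 0),
    class = "nutledger_match_report")
  report
}

#' @export
print.nutledger_match_report <- function(x, ...) {
  cat("matching report:",
      if (x$ok) "consistent" else "PROBLEMS FOUND", "\n")
  cat("  unmatched supply items:   ", length(x$unmatched), "\n")
  cat("  dangling composition ids: ", length(x$dangling), "\n")
  cat("  duplicated supply ids:    ", length(x$duplicated_supply_ids), "\n")
  cat("  coder disagreements:      ", length(x$disagreements), "\n")
  invisible(x)
}
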