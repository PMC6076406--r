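#' Assemble a pipeline configuration
#'
#' A run either generates a synthetic world (`world` arguments) or reads
#' the five input tables from CSV paths.  All randomness derives from
#' `seed`; outputs land in `out_dir` together with a manifest of input and
#' output checksums so reruns can be compared bit for bit.
#'
#' @param out_dir output directory (created if needed)
#' @param seed root seed (mandatory)
#' @param world `NULL` or a list of [world_config()] arguments (the seed is
#'   injected from `seed`)
#' @param paths `NULL` or a named list/character of CSV paths: `supply`,
#'   `composition`, `matching`, `covariates`, and optionally `intake`
#' @param stgpr a list of [stgpr_params()] arguments
#' @param nutrients nutrient ids to smooth and report
#' @param reference_year year used for quintile membership and
#'   cross-sectional correlations (default: final year)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(out_dir, seed, world = list(), paths = NULL,
                            stgpr = list(),
                            nutrients = c("energy_kcal", "carbohydrate_kcal",
                                          "protein_kcal", "fat_kcal",
                                          "mufa_kcal", "pufa_kcal",
                                          "sfa_kcal", "alcohol_kcal"),
                            reference_year = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!is.null(paths)) {
    need <- c("supply", "composition", "matching", "covariates")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop("paths lacks entries: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), world = world,
                 paths = paths, stgpr = stgpr, nutrients = nutrients,
                 reference_year = reference_year),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] fields
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

write_table <- function(x, dir, name) {
  p <- file.path(dir, name)
  write.csv(x, p, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  p
}

#' Run the full availability pipeline
#'
#' Stages: (optional) synthetic-world generation, matching validation,
#' supply-to-nutrient accounting, spatiotemporal smoothing to a complete
#' panel with uncertainty intervals, SDI and development quintiles,
#' population-weighted level aggregation, trend and substitution reports,
#' and — when survey intake is available — share validation and the
#' intake model with out-of-sample metrics.  Every output is written as
#' CSV/JSON under `config$out_dir` and checksummed in `manifest.json`.
#'
#' @param config a [pipeline_config()] (or a YAML path for
#'   [read_pipeline_config()])
#' @return invisibly, a list with all in-memory artifacts and the manifest
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$paths)) {
    wc <- do.call(world_config, c(config$world, list(seed = config$seed)))
    world <- generate_world(wc)
    supply <- world$supply; composition <- world$composition
    matching <- world$matching; covariates <- world$covariates
    intake <- world$intake; pattern <- world$pattern
    input_files <- character()
  } else {
    supply <- tibble::as_tibble(read.csv(config$paths$supply))
    composition <- tibble::as_tibble(read.csv(config$paths$composition))
    matching <- tibble::as_tibble(read.csv(config$paths$matching))
    covariates <- tibble::as_tibble(read.csv(config$paths$covariates))
    intake <- if (!is.null(config$paths$intake)) {
      tibble::as_tibble(read.csv(config$paths$intake))
    }
    pattern <- NULL
    world <- NULL
    input_files <- unlist(config$paths)
  }

  rep <- validate_matching(matching, unique(supply$item_id), composition)
  if (!rep$ok) {
    stop("stage 'matching': validation failed (",
         length(rep$unmatched), " unmatched, ", length(rep$dangling),
         " dangling)", call. = FALSE)
  }

  panel <- aggregate_availability(supply, composition, matching,
                                  check_matching = FALSE)

  params <- do.call(stgpr_params,
                    c(config$stgpr,
                      list(seed = seed_child(config$seed, 10))))
  nutrients <- intersect(config$nutrients, unique(panel$nutrient_id))
  filled <- fill_time_series(panel, covariates, params, nutrients)

  ref_year <- config$reference_year %||% max(filled$year)
  sdi <- sdi_panel(covariates)
  sdi_ref <- sdi[sdi$year == ref_year, ]
  quintiles <- assign_quintiles(sdi_ref$sdi, sdi_ref$location_id)
  agg <- aggregate_by_level(filled, quintiles,
                            covariates[, c("location_id", "year",
                                           "population")])
  trends <- trend_report(agg, year_start = min(filled$year),
                         year_end = max(filled$year))
  macro_kcals <- setdiff(grep("_kcal$", nutrients, value = TRUE),
                         "energy_kcal")
  if (length(macro_kcals) >= 2 && "energy_kcal" %in% nutrients) {
    corr <- share_correlation_matrix(filled, year = ref_year,
                                     macros = sub("_kcal$", "", macro_kcals))
    corr_df <- as.data.frame(as.table(corr$r))
    names(corr_df) <- c("nutrient_a", "nutrient_b", "r")
    corr_df$p <- as.vector(corr$p)
  } else {
    corr <- NULL
    corr_df <- data.frame(nutrient_a = character(),
                          nutrient_b = character(), r = numeric(),
                          p = numeric())
  }

  validation <- NULL
  if (!is.null(intake) && nrow(intake) > 0) {
    shares <- compare_energy_shares(panel, intake,
                                    weights = if (!is.null(pattern)) {
                                      pattern[, c("age_group", "sex",
                                                  "weight")]
                                    })
    validation <- list(
      share_diff_mean = mean(shares$diff_points),
      share_diff_max = max(shares$diff_points))
  }

  files <- c(
    availability = write_table(panel, config$out_dir, "availability.csv"),
    filled = write_table(filled, config$out_dir, "filled.csv"),
    sdi = write_table(sdi[, c("location_id", "year", "sdi")],
                      config$out_dir, "sdi.csv"),
    quintiles = write_table(quintiles, config$out_dir, "quintiles.csv"),
    aggregates = write_table(agg, config$out_dir, "aggregates.csv"),
    trends = write_table(trends, config$out_dir, "trends.csv"),
    correlations = write_table(corr_df, config$out_dir, "correlations.csv"),
    population = write_table(
      covariates[, c("location_id", "year", "population")],
      config$out_dir, "population.csv"))
  if (is.null(config$paths)) {
    files <- c(files,
               supply = write_table(supply, config$out_dir, "supply.csv"),
               composition = write_table(composition, config$out_dir,
                                         "composition.csv"),
               matching = write_table(matching, config$out_dir,
                                      "matching.csv"),
               covariates = write_table(covariates, config$out_dir,
                                        "covariates.csv"),
               intake = write_table(intake, config$out_dir, "intake.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nutledger")),
    seed = config$seed,
    reference_year = ref_year,
    nutrients = nutrients,
    inputs = as.list(tools::md5sum(input_files)),
    outputs = as.list(tools::md5sum(unname(files))),
    validation = validation)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(panel = panel, filled = filled, sdi = sdi,
                 quintiles = quintiles, aggregates = agg, trends = trends,
                 correlations = corr, validation = validation,
                 manifest = manifest, files = files, world = world))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a pipeline run
#'
#' Recomputes headline quantities from the written artifacts: global and
#' per-level energy availability at the endpoint years (reported to the
#' nearest 5 kcal), macronutrient energy shares (one decimal), and the
#' largest net changes.  The summary is recomputed from `filled.csv`,
#' `quintiles.csv` and `population.csv`, not read from the trend table, so
#' it doubles as an internal consistency check.
#'
#' @param dir a pipeline output directory
#' @return list with `energy` (per-scope start/end kcal), `shares`
#'   (per-scope final-year shares, percent), `top_changes`; printed
#'   compactly via its class
#' @export
summarise_run <- function(dir) {
  need <- file.path(dir, c("filled.csv", "quintiles.csv", "population.csv"))
  if (!all(file.exists(need))) {
    stop("missing pipeline outputs in ", dir, call. = FALSE)
  }
  filled <- tibble::as_tibble(read.csv(need[1]))
  quintiles <- tibble::as_tibble(read.csv(need[2]))
  population <- tibble::as_tibble(read.csv(need[3]))
  agg <- aggregate_by_level(filled, quintiles, population)
  y0 <- min(agg$year); y1 <- max(agg$year)
  energy <- agg |>
    dplyr::filter(.data$nutrient_id == "energy_kcal",
                  .data$year %in% c(y0, y1)) |>
    dplyr::mutate(value = report_kcal(.data$value)) |>
    tidyr::pivot_wider(names_from = "year", values_from = "value",
                       names_prefix = "kcal_")
  final <- agg[agg$year == y1, ]
  total <- final$value[final$nutrient_id == "energy_kcal"]
  names(total) <- final$scope[final$nutrient_id == "energy_kcal"]
  shares <- final |>
    dplyr::filter(grepl("_kcal$", .data$nutrient_id),
                  .data$nutrient_id != "energy_kcal") |>
    dplyr::mutate(share_pct = report_share(
      100 * .data$value / total[.data$scope])) |>
    dplyr::select("scope", "nutrient_id", "share_pct")
  trends <- trend_report(agg, y0, y1)
  top <- trends[order(-abs(trends$net_change)), ][1:min(5, nrow(trends)), ]
  structure(list(years = c(y0, y1), energy = energy, shares = shares,
                 top_changes = top),
            class = "nutledger_summary")
}

#' @export
print.nutledger_summary <- function(x, ...) {
  cat(sprintf("pipeline summary, %d-%d\n", x$years[1], x$years[2]))
  cat("energy availability (kcal/person/day, nearest 5):\n")
  print(as.data.frame(x$energy), row.names = FALSE)
  cat("final-year macronutrient energy shares (%):\n")
  print(as.data.frame(
    tidyr::pivot_wider(x$shares, names_from = "nutrient_id",
                       values_from = "share_pct")), row.names = FALSE)
  invisible(x)
}
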