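#' Domain model: pretreatment schemes, prices, and assessment context
#'
#' A *scheme* is one pretreatment applied to one feedstock with the goal of
#' isolating one lignocellulosic fraction, either in the water-insoluble
#' solid (WIS) or in the hydrolysate liquor. Schemes are represented as rows
#' of a tibble following the `schemes.csv` column schema (see
#' [load_schemes()]); the constructors below build the auxiliary value
#' objects the pipeline needs (prices, national context, enthalpies,
#' ratings, weights).
#'
#' @name scheme-model
NULL

PRETREATMENTS <- c(
  "kraft", "organosolv", "ionic_liquid", "dilute_acid", "RAAE",
  "wet_air_oxidation", "AFEX", "biological", "steam_explosion",
  "LHW", "ARP", "alkali"
)
FAMILIES  <- c("thermal", "chemical", "thermochemical", "biological")
FRACTIONS <- c("cellulose", "hemicellulose", "lignin")
LOCATIONS <- c("WIS", "liquor")

SCHEME_COLUMNS <- c(
  "id", "pretreatment", "family", "feedstock", "target_fraction",
  "target_location", "temperature_C", "pressure_bar", "residence_time_min",
  "log_severity", "ri_cellulose", "ri_hemicellulose", "ri_lignin",
  "accessibility_pct", "citation"
)

#' Default target location for a fraction
#'
#' Cellulose is valorized from the WIS; hemicellulose and lignin are
#' hydrolyzed into the liquor. An explicit override on a record is allowed.
#'
#' @param fraction One of `"cellulose"`, `"hemicellulose"`, `"lignin"`.
#' @return `"WIS"` or `"liquor"`.
#' @export
default_target_location <- function(fraction) {
  fraction <- match.arg(fraction, FRACTIONS)
  if (fraction == "cellulose") "WIS" else "liquor"
}

#' Validate a table of scheme records
#'
#' Checks the full set of record invariants: known pretreatment/family/
#' fraction/location levels, positive temperature, removal indices in
#' \[0, 100\], and unique ids. Validation is total: the first violation
#' raises a classed error naming the offending row; nothing is clamped.
#'
#' @param schemes A data frame with the `schemes.csv` columns.
#' @return The input as a tibble, invisibly usable downstream.
#' @export
validate_schemes <- function(schemes) {
  schemes <- tibble::as_tibble(schemes)
  missing <- setdiff(SCHEME_COLUMNS, names(schemes))
  if (length(missing) > 0) {
    lp_schema_error(paste0(
      "missing mandatory column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (anyDuplicated(schemes$id)) {
    lp_validation_error("scheme ids must be unique")
  }
  for (i in seq_len(nrow(schemes))) {
    row <- schemes[i, ]
    who <- sprintf("row '%s'", row$id)
    if (!row$pretreatment %in% PRETREATMENTS) {
      lp_validation_error(sprintf("%s: unknown pretreatment '%s'", who, row$pretreatment))
    }
    if (!row$family %in% FAMILIES) {
      lp_validation_error(sprintf("%s: unknown family '%s'", who, row$family))
    }
    if (!row$target_fraction %in% FRACTIONS) {
      lp_validation_error(sprintf("%s: unknown target_fraction '%s'", who, row$target_fraction))
    }
    if (!row$target_location %in% LOCATIONS) {
      lp_validation_error(sprintf("%s: unknown target_location '%s'", who, row$target_location))
    }
    if (is.na(row$temperature_C) || row$temperature_C <= 0) {
      lp_validation_error(sprintf("%s: temperature_C must be > 0", who))
    }
    for (col in c("ri_cellulose", "ri_hemicellulose", "ri_lignin")) {
      v <- row[[col]]
      if (!is.na(v) && (v < 0 || v > 100)) {
        lp_validation_error(sprintf("%s: %s = %g outside [0, 100]", who, col, v))
      }
    }
    if (!is.na(row$accessibility_pct) &&
        (row$accessibility_pct < 0 || row$accessibility_pct > 100)) {
      lp_validation_error(sprintf("%s: accessibility_pct outside [0, 100]", who))
    }
  }
  schemes
}

#' Read scheme records from CSV or JSON
#'
#' The CSV schema has columns `r paste(SCHEME_COLUMNS, collapse = ", ")`;
#' empty cells are absent values (`NA`), never zero. JSON files carry an
#' array of objects with the same fields. Every record is validated on
#' load; row order is preserved.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A validated tibble of scheme records.
#' @export
load_schemes <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) lp_io_error(sprintf("file not found: %s", path))
  if (format == "csv") {
    raw <- utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  } else {
    raw <- jsonlite::fromJSON(path)
    if (length(raw) == 0) raw <- empty_schemes()
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  }
  if (nrow(raw) == 0) {
    missing <- setdiff(SCHEME_COLUMNS, names(raw))
    if (length(missing) > 0) {
      lp_schema_error(paste0(
        "missing mandatory column(s): ", paste(missing, collapse = ", ")
      ))
    }
    return(tibble::as_tibble(raw)[, SCHEME_COLUMNS])
  }
  num_cols <- c(
    "temperature_C", "pressure_bar", "residence_time_min", "log_severity",
    "ri_cellulose", "ri_hemicellulose", "ri_lignin", "accessibility_pct"
  )
  for (col in intersect(num_cols, names(raw))) raw[[col]] <- as.numeric(raw[[col]])
  validate_schemes(raw)[, SCHEME_COLUMNS]
}

empty_schemes <- function() {
  out <- list(
    id = character(), pretreatment = character(), family = character(),
    feedstock = character(), target_fraction = character(),
    target_location = character(), temperature_C = numeric(),
    pressure_bar = numeric(), residence_time_min = numeric(),
    log_severity = numeric(), ri_cellulose = numeric(),
    ri_hemicellulose = numeric(), ri_lignin = numeric(),
    accessibility_pct = numeric(), citation = character()
  )
  tibble::as_tibble(out)
}

#' Write scheme records
#'
#' Round-trip safe with [load_schemes()]: absent values become empty cells
#' in CSV and `null` in JSON.
#'
#' @param schemes Validated scheme tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_schemes <- function(schemes, path, format = c("csv", "json")) {
  format <- match.arg(format)
  schemes <- validate_schemes(schemes)
  if (format == "csv") {
    utils::write.csv(schemes, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(schemes, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = 12)
  }
  invisible(path)
}

#' Feedstock composition (% dry basis)
#'
#' Mass composition of a lignocellulosic feedstock on a dry basis
#' (moisture is reported on a wet basis). The closure check covers the
#' five non-overlapping dry-basis fractions — cellulose, hemicellulose,
#' lignin, extractives, ash — which may sum to less than 100 (unquantified
#' material) but never more than 100.5. Fats, protein, and pectin are
#' separate characterization assays that overlap the extractive and
#' structural fractions (in the packaged rice-husk characterization they
#' would otherwise push the total past 118%), so they are stored but not
#' counted toward closure.
#'
#' @param cellulose,hemicellulose,lignin,extractives,fats,protein,pectin,ash
#'   Mass percent, dry basis.
#' @param moisture Mass percent, wet basis.
#' @return A `feedstock_composition` list.
#' @export
feedstock_composition <- function(cellulose, hemicellulose, lignin,
                                  extractives = 0, fats = 0, protein = 0,
                                  pectin = 0, ash = 0, moisture = 0) {
  out <- list(
    cellulose = cellulose, hemicellulose = hemicellulose, lignin = lignin,
    extractives = extractives, fats = fats, protein = protein,
    pectin = pectin, ash = ash, moisture = moisture
  )
  for (nm in names(out)) check_num(out[[nm]], nm, lower = 0, upper = 100)
  dry <- sum(unlist(out[c("cellulose", "hemicellulose", "lignin",
                          "extractives", "ash")]))
  if (dry > 100.5) {
    lp_validation_error(sprintf("dry-basis components sum to %.2f > 100.5", dry))
  }
  structure(out, class = "feedstock_composition")
}

#' Utility demand of one pretreatment scheme
#'
#' Hourly utility flows as reported by process simulation: cooling and
#' process water (ton/h), steam by pressure level (ton/h), electricity (kW).
#'
#' @param cooling_water_ton_h,process_water_ton_h Water flows, ton/h.
#' @param steam_lp_ton_h,steam_mp_ton_h,steam_hp_ton_h Steam flows, ton/h.
#' @param electricity_kW Electric power, kW.
#' @return A `utility_demand` list.
#' @export
utility_demand <- function(cooling_water_ton_h = 0, process_water_ton_h = 0,
                           steam_lp_ton_h = 0, steam_mp_ton_h = 0,
                           steam_hp_ton_h = 0, electricity_kW = 0) {
  out <- list(
    cooling_water_ton_h = cooling_water_ton_h,
    process_water_ton_h = process_water_ton_h,
    steam_lp_ton_h = steam_lp_ton_h, steam_mp_ton_h = steam_mp_ton_h,
    steam_hp_ton_h = steam_hp_ton_h, electricity_kW = electricity_kW
  )
  for (nm in names(out)) check_num(out[[nm]], nm, lower = 0)
  structure(out, class = "utility_demand")
}

#' Price book for operating-cost calculations
#'
#' Unit prices and operating assumptions. Steam prices default to
#' 7.89/8.07/8.15 USD per ton for low/medium/high pressure, electricity to
#' 0.1 USD/kWh, labor to one 8-hour operator shift per day at 5.21 USD/h,
#' maintenance to 6% of CapEx per year, and depreciation to the calibrated
#' fraction 0.2357 of CapEx per year (see [depreciation_cost()] for the
#' capital-recovery alternative). Water has no published unit price; the
#' default 0.09 USD/ton is an order-of-magnitude configuration value.
#'
#' @param reagent_prices Named numeric vector, USD/ton.
#' @param steam_lp,steam_mp,steam_hp Steam price, USD/ton.
#' @param electricity USD/kWh.
#' @param water USD/ton.
#' @param labor_wage USD/h.
#' @param shift_hours_per_day Hours of paid labor per day.
#' @param operating_days Days of operation per year.
#' @param operating_hours Hours of plant operation per year (continuous
#'   operation, 8760, by default).
#' @param maintenance_fraction Annual maintenance as a fraction of CapEx.
#' @param depreciation_fraction Annual depreciation as a fraction of CapEx.
#' @return A `price_book` list.
#' @export
price_book <- function(reagent_prices = NULL,
                       steam_lp = 7.89, steam_mp = 8.07, steam_hp = 8.15,
                       electricity = 0.1, water = 0.09,
                       labor_wage = 5.21, shift_hours_per_day = 8,
                       operating_days = 365, operating_hours = 8760,
                       maintenance_fraction = 0.06,
                       depreciation_fraction = 0.2357) {
  out <- list(
    reagent_prices = reagent_prices %||% numeric(0),
    steam_lp = steam_lp, steam_mp = steam_mp, steam_hp = steam_hp,
    electricity = electricity, water = water,
    labor_wage = labor_wage, shift_hours_per_day = shift_hours_per_day,
    operating_days = operating_days, operating_hours = operating_hours,
    maintenance_fraction = maintenance_fraction,
    depreciation_fraction = depreciation_fraction
  )
  for (nm in setdiff(names(out), "reagent_prices")) {
    check_num(out[[nm]], nm, lower = 0)
  }
  if (any(out$reagent_prices < 0)) lp_validation_error("reagent prices must be >= 0")
  if (out$operating_hours > 8784) {
    lp_validation_error("operating_hours cannot exceed 8784 h/yr")
  }
  structure(out, class = "price_book")
}

#' National denominators for the social indicators
#'
#' Defaults describe Colombia: industrial water withdrawal of 3.73e9 m3 in
#' 2019, renewable water availability of 2145e9 m3 (AQUASTAT), national
#' electricity of 72,824 GWh in 2021, diesel energy supply of 2.40e11 MJ in
#' 2021 (UPME), and an assumed boiler thermal efficiency of 80%.
#'
#' @param industrial_water_withdrawal_m3_yr m3/yr withdrawn by industry.
#' @param renewable_water_m3_yr m3/yr renewable availability.
#' @param national_electricity_GWh_yr GWh/yr.
#' @param national_diesel_energy_MJ_yr MJ/yr.
#' @param boiler_efficiency Fraction in (0, 1].
#' @return A `social_context` list.
#' @export
social_context <- function(industrial_water_withdrawal_m3_yr = 3.73e9,
                           renewable_water_m3_yr = 2145e9,
                           national_electricity_GWh_yr = 72824,
                           national_diesel_energy_MJ_yr = 2.40e11,
                           boiler_efficiency = 0.80) {
  out <- list(
    industrial_water_withdrawal_m3_yr = industrial_water_withdrawal_m3_yr,
    renewable_water_m3_yr = renewable_water_m3_yr,
    national_electricity_GWh_yr = national_electricity_GWh_yr,
    national_diesel_energy_MJ_yr = national_diesel_energy_MJ_yr,
    boiler_efficiency = boiler_efficiency
  )
  for (nm in names(out)) {
    if (out[[nm]] <= 0) lp_validation_error(sprintf("'%s' must be > 0", nm))
  }
  if (boiler_efficiency > 1) {
    lp_validation_error("boiler_efficiency must be in (0, 1]")
  }
  structure(out, class = "social_context")
}

#' Thermal energy delivered per ton of steam
#'
#' Configuration values (MJ/ton) on the latent-heat scale; the fossil
#' extraction indicator needs them and no published enthalpies exist for
#' these streams. Higher-pressure steam must deliver at least as much
#' energy per ton as lower-pressure steam.
#'
#' @param lp,mp,hp MJ delivered per ton of low/medium/high-pressure steam.
#' @return A `steam_enthalpy_table` list.
#' @export
steam_enthalpies <- function(lp = 2100, mp = 2000, hp = 1900) {
  if (!(hp > 0 && mp > 0 && lp > 0)) {
    lp_validation_error("steam enthalpies must be > 0")
  }
  structure(list(lp = lp, mp = mp, hp = hp), class = "steam_enthalpy_table")
}

#' Canonical order of the ten efficacy indicators
#'
#' Removal index (RI), accessibility index (AI), by-product formation
#' (HPI), inhibitor formation (IPI), technology readiness (TRLI), energy
#' demand (EI), capital cost (CapEx), operating cost (OpEx), potential
#' environmental impact (PEI), and social impact (SII). All rating rows and
#' weight vectors use this order.
#'
#' @return Character vector of length 10.
#' @export
indicator_names <- function() {
  c("ri", "ai", "hpi", "ipi", "trli", "ei", "capex", "opex", "pei", "sii")
}

#' Construct a ten-indicator rating vector
#'
#' Ratings are integers from 0 to 10 in the canonical indicator order (the
#' published matrices include a 0).
#'
#' @param ratings Numeric vector of length 10, integer-valued, in \[0, 10\].
#' @return Named numeric vector of class `indicator_ratings`.
#' @export
indicator_ratings <- function(ratings) {
  if (length(ratings) != 10) {
    lp_validation_error("exactly 10 indicator ratings are required")
  }
  if (any(is.na(ratings)) || any(ratings < 0 | ratings > 10) ||
      any(ratings != round(ratings))) {
    lp_validation_error("ratings must be integers in [0, 10]")
  }
  structure(stats::setNames(as.numeric(ratings), indicator_names()),
            class = "indicator_ratings")
}

#' Construct a weight vector (percent, summing to 100)
#'
#' @param weights Numeric vector of length 10, non-negative, summing to 100.
#' @return Named numeric vector of class `weight_vector`.
#' @seealso [weight_preset()] for the two published weightings.
#' @export
weight_vector <- function(weights) {
  if (length(weights) != 10) lp_validation_error("exactly 10 weights are required")
  if (any(is.na(weights)) || any(weights < 0)) {
    lp_validation_error("weights must be non-negative")
  }
  if (abs(sum(weights) - 100) > 1e-9) {
    lp_validation_error(sprintf("weights must sum to 100, got %.12g", sum(weights)))
  }
  structure(stats::setNames(as.numeric(weights), indicator_names()),
            class = "weight_vector")
}

#' Published weighting schemes
#'
#' `"equal"` gives every indicator 10% (the primary scheme). `"omega2"` is
#' the published statistically derived alternative
#' (8, 10, 8, 10, 12, 11, 12, 12, 15, 3)%, which emphasizes economic and
#' environmental indicators. The printed row sums to 101% despite a
#' printed total of 100; the preset rescales it to sum exactly 100 (see
#' [known_discrepancies()]).
#'
#' @param name `"equal"` or `"omega2"`.
#' @return A [weight_vector()].
#' @export
weight_preset <- function(name = c("equal", "omega2")) {
  name <- match.arg(name)
  switch(name,
    equal  = weight_vector(rep(10, 10)),
    omega2 = weight_vector(c(8, 10, 8, 10, 12, 11, 12, 12, 15, 3) / 101 * 100)
  )
}

#' Write and read efficacy results
#'
#' Results round-trip through CSV or JSON field-for-field. Scheme ids must
#' be unique within one results table.
#'
#' @param results Tibble with columns `scheme_id`, `score`, `rank`,
#'   `weight_label` (as returned by [rank_schemes()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (nrow(results) == 0) lp_validation_error("results must be non-empty")
  need <- c("scheme_id", "score", "rank", "weight_label")
  missing <- setdiff(need, names(results))
  if (length(missing) > 0) {
    lp_schema_error(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(paste(results$scheme_id, results$weight_label))) {
    lp_validation_error("duplicate scheme_id within one results table")
  }
  if (format == "csv") {
    utils::write.csv(results[, need], path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(results[, need], path, dataframe = "rows",
                         auto_unbox = TRUE, digits = 12)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
load_results <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) lp_io_error(sprintf("file not found: %s", path))
  raw <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Load a configuration file (YAML or JSON)
#'
#' Recognized top-level keys: `prices` ([price_book()] overrides),
#' `social` ([social_context()] overrides), `enthalpies`
#' ([steam_enthalpies()] overrides), and `policy` ([screening_policy()]
#' overrides). Missing keys fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `prices`, `social`, `enthalpies`, `policy`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) lp_io_error(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      lp_io_error("YAML configs require the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  list(
    prices     = do.call(price_book, as.list(cfg$prices %||% list())),
    social     = do.call(social_context, as.list(cfg$social %||% list())),
    enthalpies = do.call(steam_enthalpies, as.list(cfg$enthalpies %||% list())),
    policy     = do.call(screening_policy, as.list(cfg$policy %||% list()))
  )
}
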