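#' Social indicators for the local community
#'
#' Four indicators compare a scheme's resource use with national
#' denominators (defaults for Colombia, see [social_context()]); all are
#' expressed in percent, are zero at zero demand, and scale linearly with
#' the demand flows. Water flows are converted at 1 ton = 1 m3.
#'
#' * `water_use_sector()` — process plus cooling water over the national
#'   industrial water withdrawal.
#' * `water_use_country()` — the same numerator over the national renewable
#'   water availability; the ratio of the two indicators is therefore the
#'   fixed ratio of the two denominators.
#' * `energy_demand_share()` — electricity demand over national
#'   electricity.
#' * `fossil_extraction_share()` — diesel energy needed to raise the
#'   scheme's steam (thermal duty divided by boiler efficiency) over the
#'   national diesel energy supply.
#'
#' @param demand A [utility_demand()].
#' @param ctx A [social_context()].
#' @param operating_hours Plant operating hours per year (default 8760,
#'   continuous operation).
#' @return Percent share (numeric scalar).
#' @examples
#' d <- utility_demand(cooling_water_ton_h = 1580)
#' water_use_sector(d, social_context()) # ~0.37%
#' @export
water_use_sector <- function(demand, ctx = social_context(),
                             operating_hours = 8760) {
  check_num(operating_hours, "operating_hours", lower = 1e-12)
  w_m3_yr <- (demand$cooling_water_ton_h + demand$process_water_ton_h) *
    operating_hours
  w_m3_yr / ctx$industrial_water_withdrawal_m3_yr * 100
}

#' @rdname water_use_sector
#' @export
water_use_country <- function(demand, ctx = social_context(),
                              operating_hours = 8760) {
  check_num(operating_hours, "operating_hours", lower = 1e-12)
  w_m3_yr <- (demand$cooling_water_ton_h + demand$process_water_ton_h) *
    operating_hours
  w_m3_yr / ctx$renewable_water_m3_yr * 100
}

#' @rdname water_use_sector
#' @param electricity_kW Electric power demand, kW (taken from `demand`
#'   when a [utility_demand()] is given).
#' @export
energy_demand_share <- function(electricity_kW, ctx = social_context(),
                                operating_hours = 8760) {
  if (inherits(electricity_kW, "utility_demand")) {
    electricity_kW <- electricity_kW$electricity_kW
  }
  check_num(operating_hours, "operating_hours", lower = 1e-12)
  check_num(electricity_kW, "electricity_kW", lower = 0)
  gwh_yr <- electricity_kW * operating_hours / 1e6
  gwh_yr / ctx$national_electricity_GWh_yr * 100
}

#' @rdname water_use_sector
#' @param enthalpies A [steam_enthalpies()] table (MJ delivered per ton of
#'   steam by pressure level).
#' @export
fossil_extraction_share <- function(demand, enthalpies = steam_enthalpies(),
                                    ctx = social_context(),
                                    operating_hours = 8760) {
  check_num(operating_hours, "operating_hours", lower = 1e-12)
  thermal_mj_yr <- (demand$steam_lp_ton_h * enthalpies$lp +
                    demand$steam_mp_ton_h * enthalpies$mp +
                    demand$steam_hp_ton_h * enthalpies$hp) * operating_hours
  diesel_mj_yr <- thermal_mj_yr / ctx$boiler_efficiency
  diesel_mj_yr / ctx$national_diesel_energy_MJ_yr * 100
}

#' All four social indicators for one scheme
#'
#' @inheritParams water_use_sector
#' @inheritParams fossil_extraction_share
#' @return One-row tibble with columns `fwu_sector_pct`, `fwu_country_pct`,
#'   `ed_pct`, `ef_pct`.
#' @export
social_indicators <- function(demand, ctx = social_context(),
                              enthalpies = steam_enthalpies(),
                              operating_hours = 8760) {
  tibble::tibble(
    fwu_sector_pct = water_use_sector(demand, ctx, operating_hours),
    fwu_country_pct = water_use_country(demand, ctx, operating_hours),
    ed_pct = energy_demand_share(demand, ctx, operating_hours),
    ef_pct = fossil_extraction_share(demand, enthalpies, ctx, operating_hours)
  )
}
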