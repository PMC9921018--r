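# Rating rows in the shape rank_schemes() expects, from the packaged
# rating matrix, optionally restricted to one target-fraction block.
table7_ratings <- function(fraction = NULL) {
  t7 <- builtin_fixture("table7")
  if (!is.null(fraction)) t7 <- t7[t7$fraction == fraction, ]
  cbind(
    tibble::tibble(scheme_id = paste0(t7$fraction, "-", t7$pretreatment)),
    t7[, indicator_names()],
    tibble::tibble(total_w1 = t7$total_w1, total_w2 = t7$total_w2,
                   fraction = t7$fraction, pretreatment = t7$pretreatment)
  )
}

# The eight rows whose printed equal-weight total equals the mean of their
# printed ratings (everything else is in known_discrepancies()).
w1_consistent_rows <- function() {
  reg <- known_discrepancies()
  bad <- reg[reg$table == "table7" & reg$column == "total_w1", ]
  r <- table7_ratings()
  r[!paste(r$fraction, r$pretreatment) %in% paste(bad$fraction, bad$pretreatment), ]
}

# utility_demand from one row of the packaged utilities table
demand_from_table4 <- function(row) {
  utility_demand(
    cooling_water_ton_h = ifelse(is.na(row$cooling_water_ton_h), 0,
                                 row$cooling_water_ton_h),
    steam_lp_ton_h = row$steam_lp_ton_h,
    steam_mp_ton_h = row$steam_mp_ton_h,
    steam_hp_ton_h = row$steam_hp_ton_h,
    electricity_kW = row$electricity_kW
  )
}

zero_noise_se_profile <- function() {
  family_profile(
    "steam_explosion", "thermal", "hemicellulose",
    severity_range = c(3.1, 4.4),
    removal_response = list(
      cellulose = c(14.6, 31.3),
      hemicellulose = c(26.2, 77.9),
      lignin = c(29.7, 93.8)
    ),
    noise_sd = 0
  )
}
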