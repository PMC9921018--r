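test_that("industrial water-use share matches printed values for reproducible rows", {
  ctx <- social_context()
  d <- utility_demand(cooling_water_ton_h = 1580)
  expect_equal(water_use_sector(d, ctx), 0.371, tolerance = 0.001 / 0.371)
  expect_equal(round_half_away(water_use_sector(d, ctx), 2), 0.37)
  expect_equal(water_use_sector(utility_demand(), ctx), 0)
  # organosolv magnitude: a small unprinted process-water term is suspected
  big <- utility_demand(cooling_water_ton_h = 22200)
  expect_equal(water_use_sector(big, ctx), 5.214, tolerance = 1e-3)
})

test_that("table-4 cooling flows reproduce the printed water-withdrawal column
           outside the registry", {
  ctx <- social_context()
  t4 <- builtin_fixture("table4")
  t6 <- builtin_fixture("table6")
  reg <- known_discrepancies()
  bad <- reg[reg$table == "table6" & reg$column == "fwu_sector_pct", ]
  for (i in seq_len(nrow(t4))) {
    d <- demand_from_table4(t4[i, ])
    computed <- water_use_sector(d, ctx)
    printed <- t6$fwu_sector_pct[t6$fraction == t4$fraction[i] &
                                 t6$pretreatment == t4$pretreatment[i]]
    in_registry <- any(bad$fraction == t4$fraction[i] &
                       bad$pretreatment == t4$pretreatment[i])
    if (!in_registry) {
      expect_true(abs(computed - printed) <= 0.01,
                  label = sprintf("%s/%s: %.3f vs printed %.3f",
                                  t4$fraction[i], t4$pretreatment[i],
                                  computed, printed))
    }
  }
})

test_that("renewable-water share shares the numerator with the sector indicator", {
  ctx <- social_context()
  d <- utility_demand(cooling_water_ton_h = 1580)
  expect_equal(water_use_country(d, ctx), 6.45e-4, tolerance = 1e-2)
  expect_equal(water_use_country(utility_demand(), ctx), 0)
  # linearity: doubling the flows doubles the share
  d2 <- utility_demand(cooling_water_ton_h = 3160)
  expect_equal(water_use_country(d2, ctx), 2 * water_use_country(d, ctx))
  # denominator-ratio identity for any non-zero demand
  expect_equal(water_use_sector(d, ctx) / water_use_country(d, ctx),
               ctx$renewable_water_m3_yr / ctx$industrial_water_withdrawal_m3_yr)
})

test_that("electricity share converts kW-years to national GWh", {
  ctx <- social_context()
  expect_equal(energy_demand_share(0, ctx), 0)
  expect_equal(energy_demand_share(8589, ctx), 0.1033, tolerance = 1e-3)
  expect_equal(energy_demand_share(9.4, ctx), 1.13e-4, tolerance = 1e-2)
  # accepts a utility_demand directly
  expect_equal(energy_demand_share(utility_demand(electricity_kW = 9.4), ctx),
               energy_demand_share(9.4, ctx))
})

test_that("fossil-extraction share scales with steam duty and boiler efficiency", {
  ctx <- social_context()
  enth <- steam_enthalpies(hp = 2000)
  expect_equal(fossil_extraction_share(utility_demand(), enth, ctx), 0)
  d <- utility_demand(steam_hp_ton_h = 21.2)
  expect_equal(fossil_extraction_share(d, enth, ctx), 0.193,
               tolerance = 1e-3 / 0.193)
  # halving the boiler efficiency doubles the diesel demand
  half <- social_context(boiler_efficiency = 0.4)
  expect_equal(fossil_extraction_share(d, enth, half),
               2 * fossil_extraction_share(d, enth, ctx))
})

test_that("all four indicators are zero at zero demand and homogeneous", {
  ctx <- social_context()
  z <- social_indicators(utility_demand(), ctx)
  expect_true(all(unlist(z) == 0))
  d <- utility_demand(cooling_water_ton_h = 500, process_water_ton_h = 10,
                      steam_lp_ton_h = 4, steam_mp_ton_h = 2,
                      steam_hp_ton_h = 1, electricity_kW = 120)
  d5 <- utility_demand(cooling_water_ton_h = 2500, process_water_ton_h = 50,
                       steam_lp_ton_h = 20, steam_mp_ton_h = 10,
                       steam_hp_ton_h = 5, electricity_kW = 600)
  expect_equal(unlist(social_indicators(d5, ctx)),
               5 * unlist(social_indicators(d, ctx)))
  expect_true(all(unlist(social_indicators(d, ctx)) >= 0))
})
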