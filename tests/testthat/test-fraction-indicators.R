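test_that("removal index follows the mass-ratio definition and guards mass balance", {
  expect_equal(removal_index(100, 100), 0)
  expect_equal(removal_index(100, 90), 10)
  # rice-husk cellulose, 29.34 g/100g raw vs 26.40 g/100g pretreated
  expect_equal(removal_index(29.34, 26.40), 10.02, tolerance = 0.01 / 10.02)
  expect_error(removal_index(100, 110), class = "lignoprep_validation_error")
  expect_error(removal_index(0, 0), class = "lignoprep_validation_error")
})

test_that("accessibility indices reproduce printed screening values", {
  # liquor form: contamination by co-removed fractions
  expect_equal(accessibility_in_liquor(2.3, 12.1), 92.8)   # steam explosion
  expect_equal(accessibility_in_liquor(0, 0), 100)
  expect_equal(round_half_away(accessibility_in_liquor(9.9, 16.6), 1), 86.8)
  # WIS form: purification by removal of the others
  expect_equal(accessibility_in_wis(39.4, 84.6), 62.0)     # kraft
  expect_equal(accessibility_in_wis(75.5, 97.3), 86.4)     # wet air oxidation
  expect_equal(accessibility_in_wis(100, 100), 100)
  expect_error(accessibility_in_liquor(-1, 50), class = "lignoprep_validation_error")
  expect_error(accessibility_in_wis(50, 101), class = "lignoprep_validation_error")
})

test_that("accessibility() dispatches on target location", {
  cel <- fixture_schemes("cellulose")
  expect_equal(accessibility(cel[cel$pretreatment == "kraft", ]), 62.0)
  lig <- fixture_schemes("lignin")
  expect_equal(accessibility(lig[lig$pretreatment == "kraft", ]), 65.9)
  # symmetric record: both undesired removals equal x gives AI_wis = x
  sym <- cel[1, ]
  sym$ri_hemicellulose <- 37.5
  sym$ri_lignin <- 37.5
  expect_equal(accessibility(sym), 37.5)
})

test_that("liquor and WIS accessibility are exact complements and monotone", {
  grid <- expand.grid(r1 = seq(0, 100, by = 5), r2 = seq(0, 100, by = 5))
  liq <- accessibility_in_liquor(grid$r1, grid$r2)
  wis <- accessibility_in_wis(grid$r1, grid$r2)
  expect_equal(liq + wis, rep(100, nrow(grid)))
  # strictly monotone in each argument
  expect_true(all(diff(accessibility_in_liquor(seq(0, 100, 1), 50)) < 0))
  expect_true(all(diff(accessibility_in_wis(50, seq(0, 100, 1))) > 0))
})

test_that("severity factor matches the Overend-Chornet form", {
  expect_equal(severity_log_r0(100, 1), 0)
  expect_equal(severity_log_r0(100, 10), 1)
  expect_equal(severity_log_r0(195, 10), 3.797, tolerance = 0.001 / 3.797)
  # log10(t) at reference temperature, for a sweep of times
  t <- c(0.1, 0.5, 1, 7, 30, 240)
  expect_equal(severity_log_r0(100, t), log10(t))
  # strictly increasing in temperature and time
  expect_true(all(diff(severity_log_r0(seq(60, 220, 5), 15)) > 0))
  expect_true(all(diff(severity_log_r0(150, seq(1, 120, 2))) > 0))
  expect_error(severity_log_r0(150, 0), class = "lignoprep_validation_error")
})

test_that("screening applies strict thresholds and partitions the input", {
  cel <- fixture_schemes("cellulose")
  out <- screen(cel)
  # dilute acid: conservation 90.1 > 80 -> selected
  expect_true("cellulose-dilute_acid" %in% out$selected$id)
  # the six schemes the screening selects for cellulose isolation
  expect_setequal(out$selected$pretreatment,
                  c("kraft", "organosolv", "ionic_liquid", "dilute_acid",
                    "RAAE", "wet_air_oxidation"))
  # AFEX: conservation 72.2 < 80 -> rejected with a machine-readable reason
  afex <- out$rejected[out$rejected$pretreatment == "AFEX", ]
  expect_match(afex$reason, "conservation below threshold")
  # partition: selected and rejected are disjoint and cover the input
  expect_setequal(c(out$selected$id, out$rejected$id), cel$id)
  expect_length(intersect(out$selected$id, out$rejected$id), 0)

  # boundary: a liquor removal of exactly 60% is rejected (strict inequality)
  hem <- fixture_schemes("hemicellulose")[1, ]
  hem$ri_hemicellulose <- 60.0
  expect_equal(nrow(screen(hem)$selected), 0)
  hem$ri_hemicellulose <- 60.0 + 1e-9
  expect_equal(nrow(screen(hem)$selected), 1)
})

test_that("composition window applies only when the feedstock is known", {
  rec <- fixture_schemes("cellulose")[1, ] # kraft, conservation 90 > 80
  outside <- list("Eucalyptus globulus" = feedstock_composition(
    cellulose = 55, hemicellulose = 25, lignin = 15
  ))
  out <- screen(rec, feedstocks = outside)
  expect_equal(nrow(out$selected), 0)
  expect_match(out$rejected$reason, "composition outside window")
  inside <- list("Eucalyptus globulus" = feedstock_composition(
    cellulose = 45, hemicellulose = 25, lignin = 27
  ))
  expect_equal(nrow(screen(rec, feedstocks = inside)$selected), 1)
  # unknown feedstock: the composition check passes
  expect_equal(nrow(screen(rec, feedstocks = list())$selected), 1)
})

test_that("fraction yields follow the flow definitions", {
  expect_equal(yield_fraction("cellulose", feed_rate = 50, c6_in_wis = 10.15), 20.3)
  expect_equal(yield_fraction("hemicellulose", feed_rate = 50,
                              oligomers_c5 = 2.5, monosaccharides_c5 = 2.45), 9.9)
  expect_equal(yield_fraction("lignin", feed_rate = 50, lignin_in_liquor = 10.8), 21.6)
  expect_equal(yield_fraction("cellulose", feed_rate = 50), 0)
  expect_error(yield_fraction("cellulose", feed_rate = 50, c6_in_wis = -1),
               class = "lignoprep_validation_error")
  expect_error(yield_fraction("lignin", feed_rate = 50, lignin_in_liquor = 60),
               class = "lignoprep_validation_error")
})

test_that("recomputed accessibility matches the printed columns outside the registry", {
  reg <- known_discrepancies()
  for (tbl_name in c("table1", "table2", "table3")) {
    fraction <- c(table1 = "cellulose", table2 = "hemicellulose",
                  table3 = "lignin")[[tbl_name]]
    schemes <- fixture_schemes(fraction)
    ai <- accessibility(schemes)
    bad <- reg[reg$table == tbl_name & reg$column == "ai_printed", ]
    ok <- !paste(schemes$pretreatment, schemes$feedstock) %in%
      paste(bad$pretreatment, bad$feedstock)
    expect_true(all(abs(ai[ok] - schemes$accessibility_pct[ok]) <= 0.1),
                label = sprintf("%s rows outside the registry", tbl_name))
    # registry rows really do disagree (or cannot be checked at all)
    off <- abs(ai[!ok] - schemes$accessibility_pct[!ok])
    expect_true(all(is.na(off) | off > 0.1),
                label = sprintf("%s registry rows", tbl_name))
  }
})
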