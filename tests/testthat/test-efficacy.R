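test_that("TRL maps onto the 10-point rating scale by proportional rounding", {
  expect_equal(trl_to_rating(9), 10L)
  expect_equal(trl_to_rating(1), 1L)
  expect_equal(trl_to_rating(8), 9L)
  expect_equal(trl_to_rating(1:9),
               as.integer(round_half_away(1:9 / 9 * 10)))
  expect_error(trl_to_rating(0), class = "lignoprep_validation_error")
  expect_error(trl_to_rating(10), class = "lignoprep_validation_error")
  expect_error(trl_to_rating(4.5), class = "lignoprep_validation_error")
})

test_that("min-max rating spans the scale and respects direction", {
  expect_equal(minmax_rating(c(0, 50, 100), "benefit"), c(0L, 5L, 10L))
  expect_equal(minmax_rating(c(0, 50, 100), "cost"), c(10L, 5L, 0L))
  expect_equal(minmax_rating(rep(3.7, 4), "benefit"), rep(5L, 4))
  expect_error(minmax_rating(numeric(0)), class = "lignoprep_validation_error")
})

test_that("efficacy score is the weighted mean of ratings", {
  da <- indicator_ratings(c(9, 6, 7, 4, 9, 7, 8, 8, 6, 8))
  expect_equal(efficacy_score(da, weight_preset("equal")), 7.2)
  expect_equal(efficacy_score(indicator_ratings(rep(10, 10)),
                              weight_preset("omega2")), 10)
  # equal weights = arithmetic mean, for every packaged rating row
  r <- table7_ratings()
  m <- as.matrix(r[, indicator_names()])
  for (i in seq_len(nrow(m))) {
    expect_equal(efficacy_score(indicator_ratings(m[i, ])), mean(m[i, ]))
  }
  expect_error(efficacy_score(da, c(50, 50)), class = "lignoprep_validation_error")
})

test_that("omega2 scores stay within the printed totals for hand-checked rows", {
  r <- table7_ratings()
  w2 <- weight_preset("omega2")
  pick <- function(fr, pre) {
    row <- r[r$fraction == fr & r$pretreatment == pre, ]
    list(score = efficacy_score(indicator_ratings(
      as.numeric(row[, indicator_names()])), w2), printed = row$total_w2)
  }
  for (case in list(pick("cellulose", "dilute_acid"),
                    pick("cellulose", "wet_air_oxidation"),
                    pick("cellulose", "RAAE"))) {
    expect_true(abs(case$score - case$printed) <= 0.05)
  }
})

test_that("score is monotone in each rating and bounded by rating extremes", {
  base <- c(5, 6, 7, 4, 8, 5, 6, 7, 5, 6)
  w <- weight_preset("omega2")
  s0 <- efficacy_score(indicator_ratings(base), w)
  for (k in 1:10) {
    up <- base
    up[k] <- up[k] + 1
    expect_gt(efficacy_score(indicator_ratings(up), w), s0)
  }
  expect_gte(s0, min(base))
  expect_lte(s0, max(base))
})

test_that("ranking is deterministic, id-tie-broken, and permutation invariant", {
  lig <- table7_ratings("lignin")
  ranked <- rank_schemes(lig, weight_preset("equal"), "equal")
  expect_equal(ranked$scheme_id[ranked$rank == 1], "lignin-kraft")
  expect_equal(ranked$rank, seq_len(nrow(lig)))
  # permutation invariance
  shuffled <- lig[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(rank_schemes(shuffled, weight_preset("equal"), "equal"), ranked)
  # single scheme
  one <- rank_schemes(lig[1, ], weight_preset("equal"))
  expect_equal(one$rank, 1L)
  # identical ratings tie-break by ascending id
  twin <- lig[c(1, 1), ]
  twin$scheme_id <- c("b-scheme", "a-scheme")
  tied <- rank_schemes(twin, weight_preset("equal"))
  expect_equal(tied$scheme_id, c("a-scheme", "b-scheme"))
  expect_error(rank_schemes(lig[c(1, 1), ], weight_preset("equal")),
               class = "lignoprep_validation_error")
})

test_that("weight sensitivity is exact at p = 0 and reproducible per seed", {
  cel <- table7_ratings("cellulose")
  base_ranking <- rank_schemes(cel, weight_preset("equal"))
  s0 <- weight_sensitivity(cel, weight_preset("equal"),
                           relative_perturbation = 0, n_draws = 25, seed = 7)
  for (i in seq_len(nrow(base_ranking))) {
    f <- s0$frequency[s0$scheme_id == base_ranking$scheme_id[i] &
                      s0$rank == base_ranking$rank[i]]
    expect_equal(f, 1)
  }
  a <- weight_sensitivity(cel, n_draws = 200, seed = 42)
  b <- weight_sensitivity(cel, n_draws = 200, seed = 42)
  expect_identical(a, b)
  # frequencies are a distribution over ranks for each scheme
  expect_equal(as.vector(tapply(a$frequency, a$scheme_id, sum)),
               rep(1, length(unique(a$scheme_id))))
})

test_that("dilute acid dominates rank 1 of the cellulose block under perturbation", {
  cel <- table7_ratings("cellulose")
  s <- weight_sensitivity(cel, weight_preset("equal"),
                          relative_perturbation = 0.2, n_draws = 1000, seed = 11)
  f_top <- s$frequency[s$scheme_id == "cellulose-dilute_acid" & s$rank == 1]
  expect_gt(f_top, 0.5)
})
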