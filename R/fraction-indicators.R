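#' Removal index of a lignocellulosic fraction
#'
#' Percent of a fraction's initial dry-basis mass removed from the solid by
#' pretreatment: `RI = (1 - pretreated/raw) * 100`.
#'
#' @param raw_fraction_mass Dry-basis mass of the fraction in the raw
#'   feedstock (any consistent unit). Must be > 0.
#' @param pretreated_fraction_mass Dry-basis mass remaining in the solid
#'   after pretreatment. Must satisfy `0 <= pretreated <= raw` (a
#'   pretreatment cannot create mass).
#' @return Removal index in percent, in \[0, 100\]. Vectorized.
#' @examples
#' removal_index(29.34, 26.40) # ~10% of the cellulose removed
#' @export
removal_index <- function(raw_fraction_mass, pretreated_fraction_mass) {
  if (any(is.na(raw_fraction_mass)) || any(raw_fraction_mass <= 0)) {
    lp_validation_error("raw_fraction_mass must be > 0")
  }
  if (any(is.na(pretreated_fraction_mass)) || any(pretreated_fraction_mass < 0)) {
    lp_validation_error("pretreated_fraction_mass must be >= 0")
  }
  if (any(pretreated_fraction_mass > raw_fraction_mass)) {
    lp_validation_error(
      "pretreated mass exceeds raw mass: a pretreatment cannot create fraction mass"
    )
  }
  (1 - pretreated_fraction_mass / raw_fraction_mass) * 100
}

check_ri <- function(x, name) {
  if (any(is.na(x)) || any(x < 0 | x > 100)) {
    lp_validation_error(sprintf("'%s' must be a removal index in [0, 100]", name))
  }
  x
}

#' Accessibility indices
#'
#' How cleanly the target fraction can be valorized, given co-removal of
#' the two *undesired* fractions. For a target recovered in the liquor,
#' undesired material hydrolyzed alongside it contaminates the stream, so
#' `AI = 100 - 0.5*RI1 - 0.5*RI2`. For a target preserved in the
#' water-insoluble solid (WIS), removal of the undesired fractions purifies
#' the solid, so `AI = 0.5*RI1 + 0.5*RI2`. The two forms are exact
#' complements: they sum to 100 for any pair of removal indices.
#'
#' @param ri_undesired_1,ri_undesired_2 Removal indices (percent, in
#'   \[0, 100\]) of the two non-target fractions.
#' @return Accessibility index in percent. Vectorized.
#' @examples
#' accessibility_in_wis(39.4, 84.6)    # 62.0
#' accessibility_in_liquor(2.3, 12.1)  # 92.8
#' @export
accessibility_in_liquor <- function(ri_undesired_1, ri_undesired_2) {
  check_ri(ri_undesired_1, "ri_undesired_1")
  check_ri(ri_undesired_2, "ri_undesired_2")
  100 - 0.5 * ri_undesired_1 - 0.5 * ri_undesired_2
}

#' @rdname accessibility_in_liquor
#' @export
accessibility_in_wis <- function(ri_undesired_1, ri_undesired_2) {
  check_ri(ri_undesired_1, "ri_undesired_1")
  check_ri(ri_undesired_2, "ri_undesired_2")
  0.5 * ri_undesired_1 + 0.5 * ri_undesired_2
}

#' Accessibility index of scheme records
#'
#' Dispatches per record on `target_location`: WIS targets use
#' [accessibility_in_wis()], liquor targets [accessibility_in_liquor()],
#' with the two non-target fractions as the undesired pair.
#'
#' @param schemes Validated scheme tibble.
#' @return Numeric vector of accessibility indices (percent), one per row;
#'   `NA` where a needed removal index is absent.
#' @export
accessibility <- function(schemes) {
  schemes <- validate_schemes(schemes)
  ri <- list(
    cellulose = schemes$ri_cellulose,
    hemicellulose = schemes$ri_hemicellulose,
    lignin = schemes$ri_lignin
  )
  vapply(seq_len(nrow(schemes)), function(i) {
    undesired <- setdiff(FRACTIONS, schemes$target_fraction[i])
    r1 <- ri[[undesired[1]]][i]
    r2 <- ri[[undesired[2]]][i]
    if (is.na(r1) || is.na(r2)) return(NA_real_)
    if (schemes$target_location[i] == "WIS") {
      accessibility_in_wis(r1, r2)
    } else {
      accessibility_in_liquor(r1, r2)
    }
  }, numeric(1))
}

#' Severity factor Log(R0)
#'
#' The Overend-Chornet severity factor summarizing the hydrothermal
#' intensity of a pretreatment:
#' `Log(R0) = log10( t * exp((T - 100) / 14.75) )` with `t` in minutes and
#' `T` in degrees Celsius. At the 100 degree reference temperature it
#' reduces to `log10(t)`; it increases strictly in both arguments.
#'
#' @param temperature_C Temperature in degrees Celsius (>= 0).
#' @param time_min Residence time in minutes (> 0).
#' @return Dimensionless log10 severity. Vectorized.
#' @examples
#' severity_log_r0(100, 10) # 1
#' severity_log_r0(195, 10) # ~3.80
#' @export
severity_log_r0 <- function(temperature_C, time_min) {
  if (any(is.na(time_min)) || any(time_min <= 0)) {
    lp_validation_error("time_min must be > 0")
  }
  if (any(is.na(temperature_C)) || any(temperature_C < 0)) {
    lp_validation_error("temperature_C must be >= 0")
  }
  log10(time_min) + (temperature_C - 100) / (14.75 * log(10))
}

#' Screening policy
#'
#' The literature-curation window on feedstock composition
#' (25% < cellulose < 50%, 20% < hemicellulose < 40%,
#' 10% < lignin < 35%, dry basis) and the removal thresholds: liquor
#' targets need removal *higher than* 60%, WIS targets conservation
#' *higher than* 80%. Both thresholds are strict inequalities, so boundary
#' values are rejected.
#'
#' @param composition_window Named list of `c(min, max)` percent per
#'   fraction.
#' @param min_liquor_removal_pct,min_wis_conservation_pct Strict thresholds
#'   in percent.
#' @return A `screening_policy` list.
#' @export
screening_policy <- function(composition_window = list(
                               cellulose = c(25, 50),
                               hemicellulose = c(20, 40),
                               lignin = c(10, 35)
                             ),
                             min_liquor_removal_pct = 60,
                             min_wis_conservation_pct = 80) {
  for (f in names(composition_window)) {
    w <- composition_window[[f]]
    if (length(w) != 2 || w[1] >= w[2] || any(w < 0 | w > 100)) {
      lp_validation_error(sprintf("invalid composition window for '%s'", f))
    }
  }
  check_num(min_liquor_removal_pct, "min_liquor_removal_pct", 0, 100)
  check_num(min_wis_conservation_pct, "min_wis_conservation_pct", 0, 100)
  structure(list(
    composition_window = composition_window,
    min_liquor_removal_pct = min_liquor_removal_pct,
    min_wis_conservation_pct = min_wis_conservation_pct
  ), class = "screening_policy")
}

#' Screen scheme records for a target fraction
#'
#' A record is selected iff (a) its feedstock composition, when known,
#' lies inside the policy window (records without a composition pass this
#' check — the window was applied during literature curation, and
#' individual literature records carry no composition), and (b) the target
#' removal index strictly exceeds the liquor threshold (liquor targets) or
#' the target conservation `100 - RI` strictly exceeds the WIS threshold
#' (WIS targets). Screening is total and partitions the input: every
#' record lands in exactly one of `selected` or `rejected`, and each
#' rejection carries a machine-readable `reason`.
#'
#' @param schemes Validated scheme tibble.
#' @param feedstocks Optional named list of [feedstock_composition()]
#'   objects keyed by the records' `feedstock` strings.
#' @param policy A [screening_policy()].
#' @return List with elements `selected` (scheme tibble) and `rejected`
#'   (scheme tibble plus a `reason` column).
#' @export
screen <- function(schemes, feedstocks = NULL, policy = screening_policy()) {
  schemes <- validate_schemes(schemes)
  reasons <- character(nrow(schemes))
  for (i in seq_len(nrow(schemes))) {
    row <- schemes[i, ]
    comp <- feedstocks[[row$feedstock]]
    if (!is.null(comp)) {
      for (f in names(policy$composition_window)) {
        w <- policy$composition_window[[f]]
        if (!(comp[[f]] > w[1] && comp[[f]] < w[2])) {
          reasons[i] <- sprintf(
            "composition outside window: %s = %g not in (%g, %g)",
            f, comp[[f]], w[1], w[2]
          )
          break
        }
      }
      if (nzchar(reasons[i])) next
    }
    target_ri <- switch(row$target_fraction,
      cellulose = row$ri_cellulose,
      hemicellulose = row$ri_hemicellulose,
      lignin = row$ri_lignin
    )
    if (is.na(target_ri)) {
      reasons[i] <- "target removal index absent"
    } else if (row$target_location == "liquor") {
      if (!(target_ri > policy$min_liquor_removal_pct)) {
        reasons[i] <- sprintf(
          "removal to liquor %.1f%% not higher than %g%%",
          target_ri, policy$min_liquor_removal_pct
        )
      }
    } else {
      conservation <- 100 - target_ri
      if (!(conservation > policy$min_wis_conservation_pct)) {
        reasons[i] <- sprintf(
          "conservation below threshold: %.1f%% not higher than %g%%",
          conservation, policy$min_wis_conservation_pct
        )
      }
    }
  }
  keep <- !nzchar(reasons)
  rejected <- schemes[!keep, ]
  rejected$reason <- reasons[!keep]
  list(selected = schemes[keep, ], rejected = rejected)
}

#' Pretreatment yield of a lignocellulosic fraction
#'
#' Overall yield in kg per 100 kg of dry feedstock. Cellulose yield counts
#' the six-carbon content of the WIS; hemicellulose yield counts
#' five-carbon oligomers plus monosaccharides in the hydrolysate; lignin
#' yield counts solubilized lignin in the liquor.
#'
#' @param feed_rate Dry feedstock processing rate, ton/d (default 50).
#' @param c6_in_wis Six-carbon flow in the WIS, ton/d.
#' @param oligomers_c5,monosaccharides_c5 Five-carbon flows in the
#'   hydrolysate, ton/d.
#' @param lignin_in_liquor Solubilized lignin flow, ton/d.
#' @param target Fraction whose yield to compute.
#' @return Yield in kg per 100 kg feed.
#' @export
yield_fraction <- function(target = c("cellulose", "hemicellulose", "lignin"),
                           feed_rate = 50, c6_in_wis = 0, oligomers_c5 = 0,
                           monosaccharides_c5 = 0, lignin_in_liquor = 0) {
  target <- match.arg(target)
  check_num(feed_rate, "feed_rate", lower = 1e-12)
  for (nm in c("c6_in_wis", "oligomers_c5", "monosaccharides_c5", "lignin_in_liquor")) {
    check_num(get(nm), nm, lower = 0, upper = feed_rate)
  }
  switch(target,
    cellulose = c6_in_wis / feed_rate * 100,
    hemicellulose = (oligomers_c5 + monosaccharides_c5) / feed_rate * 100,
    lignin = lignin_in_liquor / feed_rate * 100
  )
}
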