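#' Rating direction of each indicator
#'
#' Whether a higher raw value of an indicator deserves a higher rating
#' (`"benefit"`) or a lower one (`"cost"`). Removal, accessibility,
#' by-product formation, and technology readiness are benefits; inhibitor
#' formation, energy demand, capital and operating cost, environmental
#' impact, and social impact are costs to be minimized.
#'
#' @return Named character vector over [indicator_names()].
#' @export
indicator_directions <- function() {
  c(
    ri = "benefit", ai = "benefit", hpi = "benefit", ipi = "cost",
    trli = "benefit", ei = "cost", capex = "cost", opex = "cost",
    pei = "cost", sii = "cost"
  )
}

#' Map a technology readiness level to a 0-10 rating
#'
#' TRL runs from 1 (fundamental research) to 9 (commercial application);
#' the rating scale runs to 10. The mapping is `round(trl/9 * 10)` with
#' ties going away from zero, so TRL 9 maps to 10 and TRL 8 to 9.
#'
#' @param trl Integer TRL in \[1, 9\]. Vectorized.
#' @return Integer rating in \[1, 10\].
#' @export
trl_to_rating <- function(trl) {
  if (any(is.na(trl)) || any(trl < 1 | trl > 9) || any(trl != round(trl))) {
    lp_validation_error("trl must be an integer in [1, 9]")
  }
  as.integer(round_half_away(trl / 9 * 10))
}

#' Min-max normalization of raw indicator values to integer ratings
#'
#' A reproducible default for rating novel or synthetic schemes (the
#' published ratings themselves were expert judgments and are shipped as
#' fixtures). Benefit indicators map the range \[min, max\] onto \[0, 10\];
#' cost indicators reverse it. Ties in rounding go away from zero. A
#' constant column carries no information and maps to the neutral rating 5.
#'
#' @param values Numeric vector of raw indicator values across schemes.
#' @param direction `"benefit"` or `"cost"`.
#' @return Integer ratings in \[0, 10\], same length as `values`.
#' @export
minmax_rating <- function(values, direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  if (length(values) == 0) lp_validation_error("values must be non-empty")
  if (any(is.na(values))) lp_validation_error("values must not contain NA")
  rng <- range(values)
  if (diff(rng) == 0) return(rep(5L, length(values)))
  scaled <- (values - rng[1]) / diff(rng)
  if (direction == "cost") scaled <- 1 - scaled
  as.integer(round_half_away(10 * scaled))
}

#' Weighted efficacy score
#'
#' The weighted sum of the ten indicator ratings,
#' `score = sum(w_i/100 * I_i)`, a dimensionless value in \[0, 10\]. With
#' equal weights it is exactly the arithmetic mean of the ratings.
#'
#' @param ratings An [indicator_ratings()] vector (or numeric length 10 in
#'   canonical order).
#' @param weights A [weight_vector()] (percent, summing to 100).
#' @return Dimensionless score.
#' @examples
#' r <- indicator_ratings(c(9, 6, 7, 4, 9, 7, 8, 8, 6, 8))
#' efficacy_score(r, weight_preset("equal")) # 7.2
#' @export
efficacy_score <- function(ratings, weights = weight_preset("equal")) {
  if (!inherits(ratings, "indicator_ratings")) ratings <- indicator_ratings(ratings)
  if (!inherits(weights, "weight_vector")) weights <- weight_vector(weights)
  if (length(ratings) != length(weights)) {
    lp_validation_error("ratings and weights must both have length 10")
  }
  sum(unclass(weights) / 100 * unclass(ratings))
}

ratings_matrix <- function(rows) {
  need <- c("scheme_id", indicator_names())
  missing <- setdiff(need, names(rows))
  if (length(missing) > 0) {
    lp_schema_error(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(rows) == 0) lp_validation_error("at least one rating row is required")
  if (anyDuplicated(rows$scheme_id)) lp_validation_error("duplicate scheme_id")
  m <- as.matrix(rows[, indicator_names()])
  if (any(is.na(m)) || any(m < 0 | m > 10)) {
    lp_validation_error("ratings must be in [0, 10] with no missing cells")
  }
  rownames(m) <- rows$scheme_id
  m
}

#' Score and rank a block of schemes
#'
#' Scores every scheme with [efficacy_score()], sorts descending, and
#' assigns ranks 1..n (1 = best). Ties are broken by ascending scheme id —
#' a documented, deterministic rule; reordering the input rows changes
#' neither scores nor ranks.
#'
#' @param rows Tibble with a `scheme_id` column and the ten rating columns
#'   named as in [indicator_names()].
#' @param weights A [weight_vector()].
#' @param weight_label Label recorded in the result (defaults to
#'   `"custom"`; [rank_schemes_preset()] fills in the preset name).
#' @return Tibble with columns `scheme_id`, `score`, `rank`,
#'   `weight_label`, ordered by rank.
#' @export
rank_schemes <- function(rows, weights = weight_preset("equal"),
                         weight_label = "custom") {
  if (!inherits(weights, "weight_vector")) weights <- weight_vector(weights)
  m <- ratings_matrix(rows)
  scores <- drop(m %*% (unclass(weights) / 100))
  ord <- order(-scores, rownames(m))
  tibble::tibble(
    scheme_id = rownames(m)[ord],
    score = unname(scores[ord]),
    rank = seq_along(ord),
    weight_label = weight_label
  )
}

#' @rdname rank_schemes
#' @param preset `"equal"` or `"omega2"`.
#' @export
rank_schemes_preset <- function(rows, preset = c("equal", "omega2")) {
  preset <- match.arg(preset)
  rank_schemes(rows, weight_preset(preset), weight_label = preset)
}

#' Rank stability under weight perturbation
#'
#' Draws `n_draws` weight vectors by multiplying each base weight by an
#' independent uniform factor in `[1 - p, 1 + p]` and renormalizing to
#' 100%, re-ranks the schemes under each draw, and tabulates how often
#' each scheme attains each rank. With `p = 0` every draw reproduces the
#' base ranking; results are reproducible for a fixed seed. The seed is
#' applied locally so the caller's RNG state is left untouched.
#'
#' @param rows Rating rows as for [rank_schemes()].
#' @param base Base [weight_vector()].
#' @param relative_perturbation Fraction `p` in \[0, 1).
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed.
#' @return Tibble with columns `scheme_id`, `rank`, `frequency` (fraction
#'   of draws, rows summing to 1 per scheme).
#' @export
weight_sensitivity <- function(rows, base = weight_preset("equal"),
                               relative_perturbation = 0.2, n_draws = 1000,
                               seed = 1) {
  if (!inherits(base, "weight_vector")) base <- weight_vector(base)
  check_num(relative_perturbation, "relative_perturbation", 0, 1 - 1e-12)
  check_num(n_draws, "n_draws", lower = 1)
  m <- ratings_matrix(rows)
  n <- nrow(m)
  counts <- matrix(0L, nrow = n, ncol = n,
                   dimnames = list(rownames(m), NULL))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  p <- relative_perturbation
  base_w <- unclass(base)
  for (d in seq_len(n_draws)) {
    w <- base_w * stats::runif(10, 1 - p, 1 + p)
    w <- w / sum(w) * 100
    scores <- drop(m %*% (w / 100))
    ord <- order(-scores, rownames(m))
    ranks <- integer(n)
    ranks[ord] <- seq_len(n)
    counts[cbind(seq_len(n), ranks)] <- counts[cbind(seq_len(n), ranks)] + 1L
  }
  tibble::tibble(
    scheme_id = rep(rownames(m), each = n),
    rank = rep(seq_len(n), times = n),
    frequency = as.vector(t(counts)) / n_draws
  )
}
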