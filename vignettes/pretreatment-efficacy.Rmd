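---
title: "Methods: multi-criteria efficacy assessment of lignocellulosic pretreatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-criteria efficacy assessment of lignocellulosic pretreatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignoprep)
```

## The problem

Pretreatment is the critical early stage of biorefinery design: it decides
which lignocellulosic fraction — cellulose, hemicellulose, or lignin —
becomes available for valorization, in which phase (the water-insoluble
solid, WIS, or the hydrolysate liquor), and how contaminated it arrives.
`lignoprep` implements a screening-and-ranking workflow for single-step
pretreatments: fraction-level indices, a literature screen, downstream
techno-economic and social-indicator arithmetic, and a weighted-sum
multi-criteria score that ranks candidate schemes per target fraction.

## Fraction-level model

**Removal index.** For a fraction with dry-basis mass $m_0$ in the raw
feedstock and $m_1$ remaining in the pretreated solid,
$\mathrm{RI} = (1 - m_1/m_0)\times 100\%$. Removal indices live on the
0–100 scale everywhere in the package (never 0–1), matching how the field
reports them.

**Accessibility index.** Isolating one fraction without touching the
others is impossible, so accessibility discounts the target by the
co-removal of the two *undesired* fractions with removal indices $r_1,
r_2$:

$$\mathrm{AI}_{\text{liquor}} = 100 - \tfrac12 r_1 - \tfrac12 r_2,
\qquad
\mathrm{AI}_{\text{WIS}} = \tfrac12 r_1 + \tfrac12 r_2 .$$

In the liquor, co-hydrolyzed material contaminates the stream; in the WIS,
removal of the other fractions purifies the solid. The two forms are exact
complements (they sum to 100 for any $r_1, r_2$), which the test suite
checks on a dense grid. `accessibility()` dispatches per record:
cellulose targets default to the WIS, hemicellulose and lignin to the
liquor; an explicit `target_location` override is honored.

**Severity factor.** Operating harshness is summarized by the
Overend–Chornet severity
$\log R_0 = \log_{10}\!\big(t\,e^{(T-100)/14.75}\big)$ with $t$ in minutes
and $T$ in °C. The symbol is used without definition in much of the
pretreatment literature; this package adopts the universal convention,
which reduces to $\log_{10} t$ at the 100 °C reference and reproduces the
magnitude of the severity values in the packaged screening tables
(e.g. 3.80 at 195 °C / 10 min against the printed 3.79 for wet air
oxidation, whose residence time is unreported).

**Screening.** A record passes when (a) its feedstock composition — when
known — lies inside the curation window 25 % < cellulose < 50 %,
20 % < hemicellulose < 40 %, 10 % < lignin < 35 % (dry basis), and (b) its
target removal strictly exceeds 60 % for liquor targets, or its target
conservation $100-\mathrm{RI}$ strictly exceeds 80 % for WIS targets.
Both thresholds are strict ("higher than"), so boundary values are
rejected; records without a composition pass check (a) because the window
was applied during literature curation, not per record. Screening
partitions its input: every record lands in exactly one of
`selected`/`rejected`, with a machine-readable reason.

## Efficacy score

Ten indicators are rated on an integer 0–10 scale: removal (RI),
accessibility (AI), by-product formation (HPI), inhibitor formation (IPI),
technology readiness (TRLI), energy demand (EI), CapEx, OpEx, potential
environmental impact (PEI), and social impact (SII) — always in this
canonical order. The efficacy of a scheme under a weight vector
$\omega$ (percent, summing to 100) is

$$E = \sum_{i=1}^{10} \frac{\omega_i}{100}\, I_i \in [0, 10].$$

With equal weights $E$ is exactly the mean of the ratings, an identity the
tests rely on. Ranking sorts scores descending with ties broken by
ascending scheme id — deterministic and permutation-invariant.

Two weight presets ship with the package. `"equal"` (10 % each) is the
primary scheme. `"omega2"` is the published statistically derived
alternative (8, 10, 8, 10, 12, 11, 12, 12, 15, 3) % — those printed
weights sum to 101 %, not the 100 % their source table claims, so the
preset rescales them by 100/101 to keep the weight invariant exact. The
derivation of those weights ("variability range over best case") is not
reproducible from the available data, so the package treats them as given
constants and accepts arbitrary user vectors through `weight_vector()`.

Ratings for novel or synthetic schemes can be produced reproducibly with
`minmax_rating()` (min–max onto 0–10, reversed for cost-type indicators,
ties rounded away from zero, constant columns mapped to the neutral 5) and
`trl_to_rating()` (`round(TRL/9 × 10)`). The published rating matrix
itself was expert judgment and is shipped verbatim as a fixture — the
package does not pretend to re-derive it.

## Techno-economic and social arithmetic

The process simulation that produced the utility flows and CapEx values is
out of scope; its outputs are consumed as packaged tables. Downstream of
them, all cost arithmetic is linear:

* utilities: flow × unit price × operating hours (defaults: LP/MP/HP steam
  7.89/8.07/8.15 USD/ton, electricity 0.1 USD/kWh, 8760 h/yr);
* labor: 5.21 USD/h × 8 h/d × 365 d = 15 213.2 USD/yr;
* maintenance: 6 % of CapEx per year;
* depreciation: 0.2357 × CapEx per year. This fraction is *calibrated*:
  the printed depreciation-to-CapEx ratio is ≈ 0.2357 across all 18
  schemes, close to a capital-recovery factor at 17 % over 8 years
  (0.2377) and inconsistent with plain straight-line. Both alternative
  methods are exposed in `depreciation_cost()`; the calibrated fraction is
  the default because it reproduces the published column.
* water: no published unit price exists (only a cost-index year), so
  water is a configuration input defaulting to 0.09 USD/ton, and the
  published utilities-cost column is treated as fixture data, never as a
  verification surface.

The four social indicators normalize a scheme's resource use by national
denominators (defaults for Colombia): industrial water withdrawal
3.73 × 10⁹ m³/yr, renewable water 2145 × 10⁹ m³/yr, electricity
72 824 GWh/yr, diesel energy 2.40 × 10¹¹ MJ/yr, boiler efficiency 80 %.
Water converts at 1 ton = 1 m³ and plants run 8760 h/yr — together these
reproduce the published water-withdrawal shares (0.37 %, 0.04 %, 1.00 %,
5.19 %…) from the utility flows. Steam enthalpies (LP 2100, MP 2000,
HP 1900 MJ/ton, latent-heat scale) are configuration values required by
the fossil-extraction indicator; the published ED and EF columns repeat
one value sequence across the three fraction blocks and are flagged
unreliable rather than used as oracles. No risk-scale classification is
applied: indicators compare schemes with each other, not against
thresholds.

## Fixture fidelity and the discrepancy registry

All in-scope published tables are transcribed cell-for-cell, including
accessibility and total columns that disagree with recomputation.
Disagreement is data: `known_discrepancies()` lists every such cell
(five screening-table accessibility cells, ten equal-weight totals that
differ from the mean of their own ratings by 0.1–0.4, one operating-cost
total that misses the sum of its components by 9.5 M-USD/yr, eight
water-share cells, the 101 % weight row, and one ambiguous steam-level
cell). Tests assert agreement for every row *outside* the registry and
assert disagreement (or unverifiability) *inside* it — nothing is
silently corrected, and the package always reports its own computed
values alongside the printed ones.

Two transcription judgments were needed. The lignin-table biological row
prints three numeric index cells under four columns; it is stored as the
three removal indices with the accessibility cell absent, because 95.6 %
is plausible as a biological delignification removal and no reading makes
the row satisfy the liquor formula. And the rice-husk characterization
sums to 118.5 % if every assay is counted as a dry-basis closure
component; since cellulose + hemicellulose + lignin + extractives + ash
= 99.88 %, the fats/protein/pectin assays are treated as overlapping
measurements and excluded from the closure check.

## Sensitivity analysis

`weight_sensitivity()` probes rank stability: each base weight is
multiplied by an independent uniform factor in $[1-p, 1+p]$,
renormalized to 100 %, and the block is re-ranked; the output is the
frequency with which each scheme attains each rank. By construction
weights stay non-negative for $p < 1$. With $p = 0$ every draw reproduces
the base ranking, and a fixed seed makes the whole table reproducible
(the RNG state is sandboxed so callers' streams are untouched). The
default $p = 0.2$ with 1000 draws comfortably separates stable winners —
on the packaged cellulose block, dilute acid holds rank 1 in the large
majority of draws, consistent with the observation that the equal and
statistical weightings pick the same winners.

## Synthetic data generator

The generator exists so the full pipeline is testable without external
data; it claims no thermochemical realism beyond its anchors. Each
`family_profile()` interpolates fraction removals linearly in severity
between two calibrated endpoints and adds Gaussian noise (default
3 percentage points, truncated to [0, 100]). Two default profiles are
anchored to published calibration ranges: SO₂-catalyzed steam explosion
(removals 14.6–31.3 % cellulose, 26.2–77.9 % hemicellulose, 29.7–93.8 %
lignin over severity 3.1–4.4) and recycled aqueous ammonia expansion
(hemicellulose 19.1–26.3 %, lignin 66.9–71.4 % over severity 0.2–0.7; its
unreported cellulose response is set flat at 9–11 %, matching the
screening-table magnitude). Utility demands and CapEx are drawn
log-normal (σ = 0.3) around the magnitudes of the packaged utility and
cost tables; residence times are uniform in 5–60 min (typical
pretreatment scale) and temperature is back-solved from severity. All
generators are pure functions of their parameters and seed.

What passing synthetic tests do *not* show: real removal responses are
neither linear in severity nor independent across fractions, utility
demands correlate with conditions rather than being exchangeable draws,
and expert ratings embed judgment that min–max normalization cannot
recover. The generator validates pipeline mechanics (validation,
screening guarantees, dominance recovery, determinism), not chemistry.

## Numerical choices

* Printed tables round half *away from zero* (42.75 → 42.8, 86.75 → 86.8);
  base R rounds half to even, so table comparisons use the package's
  `round_half_away()`.
* Comparisons against printed cells use ±0.1 for accessibility, ±0.05 for
  weighted totals, ±0.01 M-USD for cost components, ±0.01 percentage
  points for water shares — the printed precision of each surface.
* Absent cells ("–" in the sources) are stored as `NA`, never 0: an
  unreported pressure is not a vacuum.
* Validation is total and typed (`lignoprep_validation_error`,
  `lignoprep_schema_error`, …); nothing is clamped.
* Problem sizes: the complement-identity grid is 100 × 100, sensitivity
  checks use 200–1000 draws, synthetic blocks n ≤ 100. The full suite
  runs in a few seconds.

## Limitations

* Equipment sizing, CapEx estimation, flowsheet thermodynamics, and the
  WAR environmental-impact computation are out of scope; their outputs
  enter only as fixtures or as 0–10 ratings.
* Residence times behind the printed severity values are unreported, so
  severity can be computed for new records but not verified against the
  screening tables.
* The published ED/EF social columns and the utilities cost column cannot
  be reproduced from the published inputs under any single assumption
  this package exposes; they are flagged, not modeled.
* Labor defaults to one operator-shift per day because that is what the
  published cost rows imply, although the social-assessment text assumes
  two operators; the discrepancy is documented rather than resolved.
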