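---
title: "Growth-decline analysis of tree-ring series: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-decline analysis of tree-ring series: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dendrodecline` implements a complete dendroecological workflow for
stands in which part of the population is losing vitality: from raw
ring-width series and tree/climate metadata to divergent
growth-trajectory groups, crown-damage-dependent trend thresholds, and
crown-damage-dependent climate sensitivity of growth. This vignette
explains the statistical machinery, the tunable parameters, and the
design decisions taken where more than one defensible convention exists.

## From rings to basal area increment

Ring widths (mm, 0.01 mm resolution, Tucson `.rwl` or long CSV) are
dated by calendar year; a southern-hemisphere ring spanning the
October–March growing season is labeled by the year in which that season
*ends*, so a core taken in February 2022 ends with the 2021 ring. Cores
of one tree are averaged year-wise into a tree series
(`merge_cores_to_tree()`).

Basal area increment (BAI) is reconstructed *backwards* from the
diameter at breast height (`bai_from_dbh()`): the outermost ring's
radius is anchored at DBH/2 and radii step inward by the ring widths,

$$\mathrm{BAI}_t = \pi\,(r_t^2 - r_{t-1}^2).$$

Two conventions needed fixing here. First, no bark correction is
applied: the anchor is the over-bark DBH/2, and any innermost residual
radius (cores rarely hit the pith) simply contributes no BAI record.
Second, when the summed widths disagree with DBH/2 the package
tolerates a 25% mismatch by default (errors beyond it) and offers
proportional rescaling of the widths (`rescale = TRUE`) for users who
prefer the widths forced to the stem geometry. BAI telescopes: the sum
over any span equals $\pi(r_{\text{end}}^2 - r_{\text{start}}^2)$
exactly, which the tests exploit as an identity.

Competition is summarized by the Hegyi index over the five nearest
neighbors, $CI_i = \sum_j (dbh_j/dbh_i)/dist_{ij}$ with distances in m;
it is dimensionless and invariant to a common rescaling of all
diameters.

## Cross-dating checks and standardization

Dating quality is screened on P2YrsL-normalized series. The method name
only fixes the family ("proportion of the last two years, log"); the
exact transform adopted here is

$$p_t = \ln\!\frac{2\,w_t}{w_t + w_{t-1}},$$

which maps a constant series to 0 and drops the first year. Each series
is compared against the mean of all other normalized series; a dating
passes when the Pearson correlation exceeds 0.32 **and** Student's
$t = r\sqrt{(n-2)/(1-r^2)}$ exceeds 3.5 (both strict; $t$ is reported
as the sentinel $10^6$ when $r = 1$).

Two detrending/standardization methods are built in, both ratio-based
(index = value / fitted curve):

* **`spline32`** — a cubic smoothing spline whose frequency response is
  50% at a 32-year wavelength. It is implemented as a discrete
  second-difference penalized smoother, $(I + \lambda D'D)\,g = y$ with
  $\lambda = (2\sin(\pi/32))^{-4}$, whose response to frequency $f$ is
  exactly $1/(1 + \lambda\,(2\sin\pi f)^4)$. This closed-form
  parameterization is the standard dendro cutoff convention and makes
  the frequency response directly testable. Used for the ring-width
  index (RWI) chronology and its signal-strength statistics.
* **`mean_line`** — a horizontal line at the series mean. It removes
  only the level, retaining the full low-frequency signal, and is used
  for the climate-sensitivity analysis of slow-growing trees whose
  growth integrates multi-year climate trends.

Chronologies are per-year Tukey biweight robust means (tuning constant
9 × MAD, 10 iterations, median fallback when the MAD is 0), with the
sample depth recorded; the "reliable" span starts where at least 5
series contribute. Signal strength is summarized by the mean pairwise
inter-series correlation $\bar r$ (pairwise-complete, minimum 30 shared
years per pair) and the expressed population signal

$$\mathrm{EPS} = \frac{n\bar r}{n\bar r + 1 - \bar r},$$

with $n$ the mean per-year sample depth over the evaluated period
(not the per-year depth), and 0.85 the conventional adequacy threshold.

## Growth-trajectory groups

A PCA on the years × trees BAI matrix over the common overlap period
(years as observations, trees as variables, correlation matrix since
BAI levels differ among trees) extracts the dominant shared growth
modes. Component signs are fixed so the mean loading is positive. Each
tree is then assigned to the retained component (two by default) whose
score series it correlates with most strongly in absolute value —
absolute, because component signs are conventions; ties go to the lower
component and are flagged. Group traits (DBH, height, minimum age,
crown damage, Hegyi index, mean ring width) are compared with Welch's
t-test for DBH and Mann–Whitney rank-sum tests otherwise, matching the
variables' distributions and the unequal group sizes.

## Trends and damage thresholds

Long-term trends use the Mann-Kendall test: $S$ sums the signs of all
pairwise chronological differences; $\tau$ is the tie-corrected (tau-b)
rank correlation with time. The two-sided p-value is exact for
$n \le 10$ without ties (full Mahonian null distribution of $S$);
otherwise a normal approximation with tie-corrected variance and
continuity correction is used. The default analysis period is
1941–2021.

Per-tree $\tau$ values are regressed on each trait (OLS). Two damage
thresholds are derived: (a) the damage at which the fitted
$\tau$–damage line crosses zero — reported only when the slope is
significant at 0.1, since an insignificant line has no meaningful
crossing — and (b) the smallest damage among trees whose own trend is
significantly negative at 0.05. A loess smooth (span 0.75, degree 2 —
the span is exposed because no single value is canonical) of the site
chronology supplies a turning year, defined as the year of the smooth's
global maximum provided the smooth ends below that maximum; monotone or
flat smooths have none.

## Climate departures and the 19-month window

Station series are standardized to z-scores per calendar month over the
1992–2021 reference period (per-month climatologies remove the seasonal
cycle so departures are comparable across months); stations are then
averaged with equal weight into regional temperature and precipitation
departures, with no imputation of missing station months. The moisture
index is the precipitation minus the temperature departure: strongly
negative values flag hot-dry anomalies. Zero-precipitation months are
retained as ordinary values in the reference statistics.

Because a ring labeled $y$ integrates climate from the *previous*
growing season's October through the current season's April, the
sensitivity analysis uses a fixed 19-slot window spanning three
calendar years: October–December of $y-2$, all of $y-1$, and
January–April of $y$ (labels `prev.*`, `win.*`, `curr.*`). The mapping
is centralized in `season_window()` and pinned by an enumeration test,
because off-by-one drift here is the classic failure mode of
southern-hemisphere dendroclimatology code.

## Climate-growth sensitivity

`monthly_correlations()` computes the Pearson correlation between a
mean-line-standardized chronology and each window slot over 1931–2021,
with significance from a paired bootstrap: years are resampled with
replacement (1000 draws by default, seeded), and a slot is significant
when the 95% percentile interval of its bootstrap correlations excludes
zero. The percentile interval is mildly anticonservative at this sample
size (per-slot size ≈ 6% rather than 5% on white noise), which the
property tests account for.

Per-tree seasonal sensitivity averages the per-slot correlations of the
tree's mean-standardized BAI (e.g. December–February temperature,
January–March moisture index) — the correlations are averaged, not the
seasonal means correlated. The relation of these coefficients to crown
damage is fitted with a penalized-spline GAM (Gaussian family, basis
dimension 5 — about two dozen trees support no more — smoothing
parameter by GCV), reporting the deviance explained (the Gaussian
analogue of $R^2$) and the smooth-term p-value; both that p-value and
the per-slot bootstrap flags are reported because either could be read
as "the" significance of the damage–sensitivity link.

## The synthetic stand generator

`simulate_climate()` and `simulate_stand()` generate stands with the
statistical structure the analysis assumes, plus ground truth for
recovery tests. The defaults describe the study conditions the pipeline
is designed for: 23 trees × 2 cores, series of 140–240 years ending in
2021, and a 6-of-23 minority whose growth diverges to decline 80 years
before the end of the record.

Climate: nine stations (3 temperature, 6 precipitation) around a
cool-temperate climatology (mean annual temperature 5.2 °C with the
warmest month in January, 754 mm annual precipitation falling mostly in
winter), driven by a shared regional AR(1) monthly anomaly plus station
noise sized for an inter-station correlation of 0.8, and a post-1976
warming (+1 sd) and drying (−0.4 sd) trend reflecting the documented
regime shift in the region.

Growth, per tree, multiplicatively in log space:

* a linear age trend $J(t) = 50 + 4.5\,t$ mm² yr⁻¹ (slope varied ±40%
  per tree): with a roughly constant ring width on a growing radius,
  the BAI of an undisturbed dominant keeps rising for centuries, which
  is what keeps the healthy group's trend positive through the warming;
* climate forcing $\exp(\beta_T T_{DJF} + \beta_P P_{JJ} +
  \beta_{MI} MI_{JFM})$ with stand-level sensitivities (−0.3, 0.1, 0.3
  per sd) scaled per tree: weakly for stable trees (×0.05–0.55) and
  strongly for declining trees (×1.0–2.0), mirroring the observed rise
  of climate sensitivity with crown damage;
* a stand-wide lognormal AR(1) year effect (sd 0.25) — common weather
  influences beyond the three modeled couplings — which gives the stand
  its strong shared high-frequency signal;
* a per-tree lognormal AR(1) low-frequency factor (sd 0.25, lag-1 0.9):
  individual disturbance and micro-site history, the very thing spline
  detrending exists to remove;
* for declining trees only: an exponential trend multiplier that halves
  growth over the 80 post-divergence years, a *frozen* age trend from
  the divergence year on (a damaged crown stops expanding), and shared
  Poisson-timed stress episodes (rate 1/12 yr⁻¹, log-depth 0.3–0.9,
  6-year recovery) — synchronous damage events with slow recovery that
  bind the declining trees into a coherent trajectory of their own;
* lognormal year-to-year noise (sd 0.2) and per-core measurement noise
  (sd 0.03).

Ring widths are back-converted through the ring geometry
($r_t = \sqrt{r_0^2 + \sum \mathrm{BAI}/\pi}$ with a 2 mm pith offset)
so `bai_from_dbh()` at the recorded DBH inverts the construction
exactly. Crown damage follows
$\text{base} + \text{gain}\cdot\mathbb{1}[\text{declining}] +
\text{slope}\cdot|\beta_{T,i}| + \text{noise}$, truncated to [0, 100]
and rounded to the 5-percent classes of the field protocol. With
`couple_damage = FALSE` damage becomes pure base + noise, independent
of group and sensitivity — the specificity control for the GAM.

What the generator does **not** emulate: moth-outbreak events for the
stable group, mortality and the resulting survivor bias, rotten-stem
geometry biasing the BAI extrapolation, age estimation error, and
climate regime structure beyond one AR(1)-plus-trend anomaly per
variable. Passing recovery tests therefore show that the *methods*
recover a known structure of this kind — not that real stands are this
simple.

## Numerical choices and degenerate inputs

* Missing rings (width 0) are kept, flagged, and carry zero BAI;
  P2YrsL and spline detrending refuse zero widths where their math
  requires positivity.
* The biweight falls back to the median when the MAD is 0; a singleton
  year returns its own value.
* `crossdate_stats` caps $t$ at $10^6$ when $1 - r^2$ underflows.
* Mann-Kendall on a constant series returns $\tau = 0$, $p = 1$.
* `compare_groups` returns $p = 1$ for a trait with no variation at all.
* The GAM reports deviance explained 0 with $p = 1$ for a constant
  response.
* All stochastic steps (generator, bootstrap) take explicit seeds, and
  the pipeline derives per-analysis bootstrap seeds from the single run
  seed, so a rerun with the same config is byte-identical.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
default 23-tree stand (series up to 240 years, 1000-fold bootstrap in
the pipeline, 400-fold in the property checks) and evaluate the
end-to-end recovery properties over 50 generator seeds (coupled) plus
50 more with damage decoupled; these sizes keep the whole suite to a
few minutes on one core while leaving the binomial noise of the rate
estimates well below the margins being asserted.

## Known limitations

Heidelberg/.fh input, rotation of PCA components, change-point tests
beyond the loess turning point, response-function (multiple-regression)
coefficients, moving-window sensitivity analyses, and gap-filling or
homogenization of station climate are out of scope. The replication
deposit of the motivating study (doi:10.25625/IQ2LB6) is not
redistributed; the pipeline reads its tables through the long-CSV
readers once pointed at a local copy.
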