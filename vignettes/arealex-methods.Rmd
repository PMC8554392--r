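---
title: "Methods: small-area life expectancy estimation with arealex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area life expectancy estimation with arealex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Death counts in a small area (a few thousand residents), a single age group
and a single calendar year are tiny — often zero — so crude death rates
computed cell by cell are dominated by Poisson noise. Yet policy questions
about geographical health inequality need exactly these small-area,
year-by-year quantities: life expectancy at birth per area and year, its
trend, and the gap between the best- and worst-off areas. `arealex`
implements the standard solution: a Bayesian hierarchical model that shares
information across age groups, years and nearby areas, followed by
life-table computation on every posterior draw.

## The model

For one sex, let $y_{amt}$ and $P_{amt}$ be deaths and mid-year population
in age group $a$, area $m$ and year $t$ (year index centred at the midpoint
of the period). The death rate $\lambda_{amt}$ follows a Poisson
log-linear model:

$$y_{amt} \sim \mathrm{Poisson}(P_{amt}\,\lambda_{amt})$$

$$\log \lambda_{amt} = \alpha_a + \beta_a t
 + (\theta_m + \theta_{d(m)} + \theta_{r(m)})
 + (\phi_m + \phi_{d(m)} + \phi_{r(m)})\,t
 + \xi_{am} + \nu_{at} + \omega_{mt}$$

* $\alpha_a$, $\beta_a$: age-specific levels and linear time trends with
  first-order random-walk (RW1) priors over the age index, so the age curve
  of mortality is smooth and implausible age patterns are penalised.
* $\theta$, $\phi$: intercept and slope deviations at three nested
  geographic levels (area within district within region), each a zero-mean
  Gaussian with its own scale. A small area therefore borrows strength
  first from its district, then from its region.
* $\xi_{am}$: independent Gaussian age–area interactions, letting each area
  have its own age pattern.
* $\nu_{at}$, $\omega_{mt}$: non-linear time effects per age group and per
  area, RW1 over years.

The sexes are modelled independently throughout, because both the level
and the trend of mortality differ by sex.

### Identifiability

The time walks $\nu$ and $\omega$ are constrained to sum to zero over time
for each age group / area, otherwise they would absorb the intercepts and
linear trends. They are parameterised as a walk anchored at zero and then
centred, which enforces the constraint to machine precision in every draw
(the synthetic-data generator uses the identical construction). The age
walks $\alpha$ and $\beta$ carry the overall level and trend of log rates,
so they are not centred; weak Gaussian anchors on their first elements
(`anchor_alpha_sd = 10`, `anchor_beta_sd = 1`) make the prior proper. The
nested deviations $\theta,\phi$ and interactions $\xi$ are zero-mean by
prior only; the strongly informed age effects absorb any residual mean.

### Priors and parameterisation

Each variance component's scale gets a half-normal prior; defaults are 1
for the $\alpha$ walk, 0.5 for intercept-like components
($\theta$, $\xi$, $\nu$, $\omega$) and 0.1 for slope-like components
($\beta$ walk, $\phi$; per-year log-rate units). These are weakly
informative on the scale of log death rates and are all overridable via
`model_config()`; a component can also be held at a fixed value
(`fixed_sigma`), which is how simulation studies with known
hyperparameters are run. All zero-mean Gaussian components and the
$\beta$ and time walks use a non-centred parameterisation (effect =
scale × standard-normal), which avoids the funnel geometry that otherwise
appears when per-cell information is weak — the typical regime at median
area populations around 8000.

### Sampling

`fit_mortality()` uses a built-in No-U-Turn sampler (slice variant, dual
averaging to a target acceptance of 0.9, diagonal mass-matrix adaptation
in expanding warmup windows) written in C++. Defaults are 4 chains, 1000
warmup iterations and 1000 total retained draws; reduced settings are used
in the test suite. Convergence is summarised by split R-hat and effective
sample size on the age effects, the scale parameters and the log
posterior; a fit that exceeds the thresholds is flagged in the returned
object and printed summaries, never rerun silently. Gradients of the log
posterior are analytic and verified against finite differences in the test
suite.

## Preprocessing

Two repair rules mirror how stratified civil-registration counts behave in
practice:

* **Population repair.** Because population and death statistics are
  produced independently, a few cells can have more deaths than residents;
  `repair_population()` sets population equal to deaths in those cells.
  The model requires repaired data (deaths ≤ population in every cell).
* **Outlier-year interpolation.** A localised mass-fatality event makes
  one year a trend outlier for its area and destabilises the fitted trend.
  `interpolate_outlier_year()` replaces that area-year's deaths, for each
  sex and age group, by the mean of the two neighbouring years; the signed
  differences (actual − interpolated) are stored and added back to
  posterior *expected deaths* after fitting (`add_back_outlier()`), so the
  deaths are counted in the year they occurred. Add-back operates on
  expected deaths rather than latent rates because the protocol is a
  statement about death counts; rates for the adjusted cells are then
  re-derived as adjusted deaths / population. Interpolated counts can be
  non-integer (mean of two integers); the Poisson likelihood is evaluated
  at half-to-even rounded counts.

## Life tables

`life_table()` builds an abridged table on the groups 0, 1–4, 5–9, …,
80–84, 85+ from central death rates $m_x$, with
$q_x = n m_x / (1 + (n - a_x) m_x)$ for closed intervals. Two
person-years conventions are available:

* `"cd"` (default): $a_0$ from a Coale–Demeny-style piecewise formula in
  the infant death rate (sex-specific constants; e.g. female
  $a_0 = 0.053 + 2.8\,m_0$ below $m_0 = 0.107$), $a_x = n/2$ elsewhere.
* `"constant-hazard"`: $q_x$ and $a_x$ exactly consistent with a constant
  hazard within the interval ($q_x = 1 - e^{-n m_x}$,
  $L_x = d_x / m_x$). With this convention the table reproduces the exact
  expectation of a piecewise-constant-hazard survival model, which is what
  the microsimulation oracle in the test suite simulates; the two
  conventions differ by far less than cross-area differences of interest.

The terminal group is closed with $q = 1$, $L = l/m$.

### Kannisto–Thatcher extension

The open-ended 85+ group compresses all old-age mortality into one
interval, which biases $e_0$ comparisons when old-age mortality differs
across areas. `kt_extend()` fits the logistic hazard
$\mu(x) = a e^{bx}/(1 + a e^{bx})$ — whose logit is linear in age — to the
rates of the 70–74, 75–79 and 80–84 groups by least squares on the logit
scale at group midpoints, extrapolates rates for 85–89 … 105–109 and
110+, and rescales them (iteratively, with constant-hazard person-years as
exposure weights, i.e. matching $1/e_{85}$ of the extension) so their
aggregate equals the observed 85+ rate. Degenerate inputs (non-positive
slope, rates outside (0,1)) raise a fallback flag and leave the terminal
group unexpanded rather than extrapolating nonsense. The fitting window
and extension are conventional choices, isolated behind arguments.

Life tables are computed **per posterior draw** (vectorised across draws ×
areas × years), never only at posterior-median rates: credible intervals
for $e_0$, for interval death probabilities
($(l_{x_1} - l_{x_2})/l_{x_1}$ at interval boundaries, no sub-interval
interpolation) and for all downstream summaries require draw-level
propagation.

## Summaries

All summaries are pure functions of the $e_0$ draw cube:

* Percentiles (medians, 95% credible intervals as the 2.5th–97.5th
  percentiles, the 1st/99th cross-area percentiles) use linear
  interpolation between order statistics (R type 7) throughout.
* Cross-area gaps (max−min and p99−p1) are computed **within each draw**,
  then summarised across draws — this preserves credible intervals on the
  gaps themselves.
* The posterior probability that $e_0$ increased between two years is the
  fraction of paired draws with a higher later value; exact ties count
  one half, so P(increase) + P(decrease) = 1 and the measure is symmetric
  under exchanging the years.
* A "declining" area has a negative posterior-median change over a period.
* The sex comparison reports the cross-area Pearson correlation of
  posterior-median $e_0$ and counts areas in female-advantage bands
  (male advantage, <1, 1–5, >5 years), which partition the areas.
* The deprivation association uses a locally weighted (tricube) degree-1
  smoother of posterior-median $e_0$ against the deprivation rank
  (delegated to `stats::loess`), with a configurable span; the smoothing
  span is a presentation choice, not an estimate.

## The synthetic-data generator

The real inputs (civil-registration death records, official mid-year
population estimates) are access-restricted, so the generator is a
first-class module producing data with the generative structure the model
assumes: it draws the same latent components as the model (same
random-walk constructions, same nesting) and adds a Poisson observation
layer. Defaults describe the study conditions the package is tested
under:

* a J-shaped England-like baseline age curve (`baseline_rates_england()`),
  male rates offset upward by 0.45 on the log scale (about a 4-year
  life-expectancy gap);
* a secular mortality decline of 2% per year in every age group;
* area populations log-normal around a median of 7985 with log-SD 0.25,
  split evenly between the sexes and allocated over age groups by a fixed
  pyramid;
* cross-area heterogeneity
  ($\sigma_{\theta,\text{area}} = 0.28$, district 0.15, region 0.08,
  $\sigma_\xi = 0.10$, slope SDs 0.004/0.002/0.001 per year, time-walk
  increment SDs 0.012) calibrated once so that life expectancy spans
  roughly 70–95 years across a large set of areas — the magnitude of
  small-area inequality reported for English small areas.

What the generator does **not** emulate: real geographic boundaries or
spatial autocorrelation beyond the nesting (no conditional-autoregressive
structure), migration, cohort effects, age misstatement at old ages, or
population-estimate error. Passing recovery tests on synthetic data
therefore shows the estimation machinery is correct under the model's own
assumptions, not that the model is adequate for any particular real
dataset.

## Numerical and test-design choices

* Deterministic seeding everywhere: every generator operation takes an
  explicit seed and is bit-reproducible; the sampler uses its own
  counter-based RNG seeded from `model_config(seed)`, so pipeline reruns
  with one seed reproduce summaries exactly.
* The test suite runs reduced problem sizes chosen to exercise the full
  study structure at desk scale: parameter recovery uses a simulated
  dataset of 60 areas (2 regions × 3 districts × 10 areas) × 19 age
  groups × 18 years at median population 7985 with 2 chains × 200
  retained draws (coverage pooled over all 20 520 cells); the
  change-probability calibration uses 100 areas × 8 years under a
  stationary null and under a planted ~+2-year trend with populations of
  10^6; the shrinkage check runs 50 instances of 12 areas (two districts
  of six) × 8 years on a coarse 5-group age specification — shrinkage is
  a property of pooling across areas, not of age resolution — with one
  area at 1/100th of its five district peers' population, enough peers
  that the empirical district rate is a meaningful shrinkage target.
  Statistical bands (95% CrI coverage within [90%, 98%], calibration of
  P(increase) around 50%, etc.) are properties of the method, not of the
  reduced sizes.
* With two areas, the interpolated 1st–99th percentile gap equals 0.98 ×
  the max−min gap (a direct consequence of the type-7 percentile rule);
  with one area or one year the model pins the then-unidentifiable
  components (slopes, walks, interactions) at zero.
* `loess` at span 1 is close to, but not identical to, a global
  least-squares line (tricube weights still apply); tests compare against
  ordinary least squares with a correspondingly loose tolerance.

## Limitations

* No spatial prior beyond the administrative nesting: two adjacent areas
  in different districts share only region- and national-level
  information. A conditional-autoregressive variant is out of scope.
* The model borrows strength strongly when populations are small;
  cross-area variation is therefore somewhat attenuated (shrinkage), and
  true inequality is if anything larger than estimated — the direction of
  this effect is checked, not removed.
* Non-integer interpolated counts are rounded before entering the Poisson
  likelihood; for realistic counts the effect is far below posterior
  uncertainty.
* The sampler is a single-machine implementation; runtimes grow roughly
  linearly in cells × draws, and national-scale problems (thousands of
  areas) would need longer runs than the desk-scale settings used here.
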