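---
title: "Methods: quantal toxicity, regeneration and growth endpoints in Hydra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantal toxicity, regeneration and growth endpoints in Hydra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydratox)
```

`hydratox` analyses the four endpoints of a whole-organism nanotoxicity
study in *Hydra vulgaris*: ordinal morphology scores, quantal mortality
(LC50/LT50), tentacle regeneration after bisection, and population growth
by budding. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## Morphology scores and the death rule

Animals are scored daily on the ordinal 1–10 Wilby scale (10 = fully
extended polyp with active tentacles, 1 = complete disintegration). The
scale is an input: the package does not re-define the visual criteria of
each level. Because *Hydra* can recover from sublethal damage, an animal
counts as dead at an observation time when its score at that time is
**strictly below** the death threshold (default 4); death is evaluated per
time point and never latched across times. Whether the original assay
latched death once observed is not documented; per-time evaluation is the
choice here because it is the only one consistent with tracking recovery.

`quantal_from_scores()` turns a score panel at one time into a quantal
mortality table (one binomial group per concentration), which conserves
animals by construction: the group sizes sum to the number of score
records at that time.

Median scores across concentrations are compared with a Friedman rank
test (`friedman_scores()`), blocking on observation time by default
(24/48/72 hr replications of the same concentration series). Ordinal
scores tie heavily, so within-block ties take mid-ranks and the statistic
uses the tie-corrected denominator
$\chi^2_F = (k-1)\sum_j (R_j - b(k+1)/2)^2 / (\sum_{ij} r_{ij}^2 -
bk(k+1)^2/4)$, which reduces to the textbook
$12\sum_j R_j^2/(bk(k+1)) - 3b(k+1)$ without ties. For designs with
$bk \le 12$ an exact permutation p-value is enumerated alongside the
chi-square approximation. The chi-square approximation is known to be
coarse near the centre of the exact null distribution at few blocks
(deviations up to ~0.13 at $b = 6$, a property of the approximation, not
of this implementation); it tracks the exact tail well where decisions
are made, which is what the test suite asserts.

## Trimmed Spearman-Karber LC50 and LT50

The tolerance distribution is summarised distribution-free. Working scale
is log10 of concentration (nM) or time (hr); results are back-transformed
for reporting. The steps of `estimate_lc50()` / `estimate_lt50()`:

1. **Monotone smoothing** (`smooth_monotone()`): observed dead fractions
   are replaced by their weighted least-squares non-decreasing fit via
   pool-adjacent-violators, with group sizes as weights. Monotone input is
   unchanged; pooled blocks carry their weighted mean, so the fit is
   idempotent and conserves the weighted mean within each block.
2. **Optional trimming** (`trim_curve()`, fraction $\alpha$): the curve
   tails below $\alpha$ and above $1-\alpha$ are discarded, the crossing
   positions found by linear interpolation on the $(x, p)$ polyline are
   inserted as new endpoints, and the retained response is rescaled to
   $p' = (p-\alpha)/(1-2\alpha)$. The default is $\alpha = 0$ (no
   trimming): the published analyses invoke the trimmed method without
   stating a level, and 0 keeps the estimate fully reproducible while the
   trim machinery remains available (`--trim`) and tested. On flat
   segments the lower boundary takes the last attainment of $\alpha$ and
   the upper boundary the first attainment of $1-\alpha$, keeping the
   trim symmetric under axis reflection.
3. **Median** (`sk_log_median()`): $m = \sum_i (p_{i+1}-p_i)
   (x_i+x_{i+1})/2$, which equals $x_{\text{last}} - \int p\,dx$
   (summation by parts); the suite checks this identity to $10^{-9}$ on
   random curves.
4. **Confidence interval** (`sk_confidence()`): delta-method variance
   $V = \sum_i p_i(1-p_i)(x_{i+1}-x_{i-1})^2/(4(n_i-1))$ over interior
   groups (terminal groups have $p(1-p)=0$ on an estimable curve), with
   bounds $10^{m \pm z\sqrt V}$.

**Endpoint handling.** If the smoothed curve does not reach 0% at the low
end or 100% at the high end of the tested range, the median is reported
*not estimable* — a reportable outcome, not an error — because computing
it would require extrapolating beyond the data. With
`run_config(extend = TRUE)` the conventional anchors are assumed instead:
0% one log-step below the lowest group and 100% one log-step above the
highest, with the step taken from the adjacent design interval. The
default is the conservative no-extrapolation behaviour; the
parameter-recovery simulations in the test suite enable the extension
because a binomial top group of 20 animals at ~99% true mortality fails
to reach 100% observed in a fifth of runs even when the design brackets
the median well, and discarding those runs would bias recovery summaries.

**LT50 construction.** For one fixed concentration, dead counts
accumulate over observation times (same animals, cumulative counts); the
identical estimator then runs on log10 time. Non-monotone counts (from
recovery under a per-time death rule) are handled by the same smoothing
step.

Replicate wells at the same concentration are pooled into a single
binomial group before estimation — a choice, since the original
combination rule is not documented, justified by the exchangeability of
animals across wells at one concentration.

## Tentacle regeneration index

After bisection, regenerating tentacles are binned daily into 5 relative
length classes (1/8, 1/4, 1/2, 3/4, 1 of full length; nearest class wins,
exact midpoints go to the lower class). The per-polyp index is
$R = \sum_{K=1}^5 p_K\, n_K / n_{\max}$ with $n_{\max} = 8$, the maximal
tentacle count of an intact polyp. The class weights $p_K$ default to the
class lengths themselves, which is the only choice under which the index
reads as "average tentacle length per polyp relative to the maximum,
equal to 1 when regeneration is complete"; they are configurable for
sensitivity analysis. A polyp bearing more than 8 tentacles yields an
index above 1, reported with a warning and not clamped: $n_{\max}$ is a
physiological reference, not an algebraic bound.

Groups of 4 polyps are summarised by the arithmetic mean and sample SD at
each observation day (days 0–14). Treatments are compared per day with an
unpaired two-sample t-test, pooled-variance by default (the common
reading of "unpaired t-test"; Welch by flag). Day-by-day comparison
across 14 days raises a multiplicity question the original analysis does
not address; `compare_tri_profiles()` therefore reports both raw and
Holm-adjusted p-values and takes no position.

## Population growth

Counts start from $n_0 = 4$ founders; the model is $\ln(n/n_0) = kt$, so
the log count ratio is linear through the origin, and the doubling time
is $T_2 = \ln 2 / k$, computed analytically from $k$ rather than read off
the curve (equivalent under the model, and deterministic). The default
fit is through the origin because the model has no intercept; a
free-intercept fit is available by flag. Day-0 rows satisfy $y(0) = 0$
identically by construction, so under the through-origin model they carry
neither slope information nor noise and are excluded from residual
degrees of freedom — including them would understate the residual
variance of every fit.

Equality of growth constants between two populations is tested as the
time-by-group interaction of a pooled regression (the standard
slope-heterogeneity / ANCOVA interaction F-test); this is the
operationalisation of the published "two-way ANOVA on regression slopes".
Noiseless series with different slopes leave zero residual; the p-value
is then reported as 0. The simulated-null rejection rate of this test at
$\alpha = 0.05$ sits at the nominal level (checked over 500 runs in the
suite).

## Synthetic bioassay generator

The generator provides data with the statistical structure the analyses
assume, plus known ground truth for recovery testing. Every generator is
a pure function of (parameters, seed) and leaves the global RNG state
untouched.

- **Quantal mortality at one time** (`sim_quantal()`): binomial deaths
  with $p(d) = 1/(1+(\mathrm{LC50}/d)^{h})$ (log-logistic tolerance,
  median exactly LC50; probit optional). Spearman-Karber is
  distribution-free, so any smooth tolerance CDF serves; log-logistic is
  the default for its closed-form median.
- **Joint dose-time mortality** (`sim_timecourse()`): each animal draws
  one log-logistic lifetime whose median follows the power law
  $\mathrm{med}(d) = \mathrm{LT50}_{\mathrm{ref}}
  (d/d_{\mathrm{ref}})^{-\gamma}$. Cumulative dead counts are tallied at
  each observation time, so the per-time dose curves and per-dose time
  curves are marginals of the same animals: LC50 falls with observation
  time and LT50 falls with dose by construction.
- **Scores** (`sim_scores()`): score trajectories are tied to the same
  latent lifetimes (same seed, same draw order), decaying from 10 and
  crossing below 4 exactly at the death time, with ±1 ordinal observation
  noise that never crosses the alive/dead boundary. Score-derived death
  sets therefore coincide exactly with lifetime-based ones, mirroring the
  derivation of mortality from scores in the assay.
- **Regeneration** (`sim_regeneration()`): per polyp, 8 tentacle
  emergence times with exponential spacings (mean spacing
  `delay_factor / emergence_rate`); each tentacle elongates logistically
  with age (half length at `half_age` days) and is binned by
  `length_class()`. A treatment acts as `delay_factor` ≥ 1 on emergence
  spacing; `delay_factor = 1` reproduces the control distribution
  exactly, and delayed groups show lower mean TRI early with the gap
  closing by day 14.
- **Budding growth** (`sim_population()`): a Yule birth process (every
  individual buds independently at rate $k$, so
  $E[n(t)] = n_0 e^{kt}$) or a deterministic rounded exponential.

**Default study conditions.** Groups of 20 animals; doses 50–1000 nM;
observation times 12–96 hr; lifetime shape 4 (a realistic steepness for
an acute assay: roughly a threefold spread between the 10th and 90th
lifetime percentiles); 4 polyps per regeneration group over days 0–14;
emergence and elongation rates of 1.2/day so an untreated polyp
approaches its full tentacle crown within the 14-day window; 4 founders
and ~0.3/day control growth (doubling in ~2.3 days). The two shipped
treatment scenarios anchor their lifetime models to the published median
pairs: the TGA arm uses LT50 36 hr at 300 nM with
$\gamma = \ln(36/24)/\ln(500/300) \approx 0.794$, the GSH arm LT50 63 hr
at 500 nM with $\gamma = \ln(63/32)/\ln 2 \approx 0.978$. These are
scenario inputs for qualitative end-to-end demonstration — the raw
per-dose counts behind the published tables were never released, so exact
numeric reproduction of those tables is not a testable target.

**What the generator does not emulate:** mechanistic toxicokinetics
(ion release, oxidative stress), between-experiment batch variability,
observer drift in scoring, feeding effects on budding, or any spatial
patterning of regeneration. Passing recovery tests therefore demonstrate
estimator correctness under the stated sampling models, not robustness
to those real-data complications.

## Problem sizes in the test suite

The suite uses 500 simulated assays for LC50 recovery and CI coverage,
200 for LT50 recovery, 500 nulls for the slope-test rejection rate,
1000 random curves for the median identity, 500 random weighted inputs
for the isotonic-fit oracle, and 200 paired scenario runs for the
ordering checks — sizes at which the Monte-Carlo error of each summary is
comfortably below the band it is checked against.

## Known limitations

- The delta-method CI is a large-sample approximation; with very few
  informative groups it can undercover, which is why coverage is checked
  empirically in the suite.
- Not-estimable outcomes are reported, never silently extrapolated; users
  who want the conventional extension must opt in.
- The exact Friedman permutation is enumerated only for $bk \le 12$
  (product space up to ~2 million orderings); larger designs rely on the
  chi-square approximation.
- Scenario calibration fixes two parameters per arm from published
  medians; the remaining generator parameters are documented assumptions.
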