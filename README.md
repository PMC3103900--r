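# hydratox

Analysis pipeline for whole-organism toxicity bioassays in the freshwater
polyp *Hydra vulgaris*, the kind of study used to rank the acute and
sublethal toxicity of engineered nanomaterials (e.g. surface-capped CdTe
quantum dots) on an intact animal. The package covers the four standard
endpoints of such a study and a synthetic bioassay generator with known
ground truth.

## What it computes

**Morphology scores → mortality.** Animals are scored on the ordinal 1–10
Wilby scale (10 = healthy extended polyp). An animal counts as dead at an
observation time when its score is strictly below 4 (configurable);
`quantal_from_scores()` turns a score panel into per-concentration
dead/alive counts. Median scores across concentrations are compared with a
tie-corrected Friedman rank test, with an exact permutation p-value for
small designs.

**LC50 / LT50 by trimmed Spearman-Karber.** For a quantal series on dose
(or cumulative deaths on time), the observed dead fractions are made
monotone by weighted pool-adjacent-violators, optionally trimmed at
(α, 1−α), and the log10 median is

    m = Σ_i (p_{i+1} − p_i) · (x_i + x_{i+1})/2

with delta-method variance
`V = Σ p_i(1−p_i)(x_{i+1}−x_{i−1})²/(4(n_i−1))` and confidence bounds
`10^(m ± z√V)`. A curve that never reaches 0% or 100% within the tested
range is reported *not estimable* unless the conventional one-log-step
extension is enabled.

**Tentacle regeneration index (TRI).** Regenerating tentacles are binned
into 5 relative-length classes (1/8, 1/4, 1/2, 3/4, 1); the per-polyp
index is `R = Σ_K p_K n_K / n_max` with `n_max = 8`, so 0 = nothing
regenerated and 1 = regeneration complete. Group profiles over 14 days are
compared day-by-day with unpaired t-tests (raw and Holm-adjusted p).

**Population growth.** Budding counts from n0 = 4 founders follow
`ln(n/n0) = k t`; `fit_growth()` estimates the growth constant k and
doubling time `T2 = ln 2 / k`, and `compare_growth()` tests slope equality
between treatments via the ANCOVA interaction F-test.

## Worked example

```r
library(hydratox)

qs <- quantal_series(c(50, 100, 200, 400), rep(20, 4), c(0, 4, 16, 20),
                     axis = "dose", label = "TGA-QDs")
estimate_lc50(qs, run_config())
#> LC50 [TGA-QDs] = 141.4 nM, 95% CI (118.6, 168.7), SE(log10) = 0.03907
```

The response here is symmetric about the 100–200 nM interval, so the
Spearman-Karber median is their geometric mean √(100·200) ≈ 141.4 nM; the
interval reflects binomial sampling noise of 20 animals per group on the
log10 scale.

A full synthetic assay from a shipped scenario (an arm calibrated to a
thioglycolic-acid-capped quantum dot, with lifetime medians anchored at
LT50 = 36 hr at 300 nM):

```r
sc  <- read_scenario(system.file("extdata", "scenario_tga_qd.yaml",
                                 package = "hydratox"))
sim <- simulate_scenario(sc, seed = 1)

estimate_lc50(sim$timecourse$per_time[["72hr"]], run_config(extend = TRUE))
#> LC50 [TGA-QDs] = 124.2 nM, 95% CI (105.1, 146.7), SE(log10) = 0.03702
estimate_lt50(sim$timecourse$per_dose[["500nM"]], run_config(extend = TRUE))
#> LT50 [TGA-QDs 500 nM] = 23.18 hr, 95% CI (19.85, 27.07), SE(log10) = 0.03436

mean_tri(tri_profiles(sim$tentacles), 7)
#> $mean [1] 0.3164062   $sd [1] 0.1334238   $n [1] 4
```

The estimated LC50 at 72 hr (≈124 nM) sits below the 48-hr value and the
LT50 at 500 nM (≈23 hr) below the 300-nM reference median, reproducing the
dose- and time-dependence the assay is designed to detect; the mean TRI of
0.32 at day 7 says the 4-polyp group has regenerated about a third of its
full tentacle crown.

A command-line front end wraps the same functions:

```sh
hydratox simulate --scenario inst/extdata/scenario_tga_qd.yaml --seed 1 --out assay/
hydratox lc50 --in assay/quantal.csv --extend --out lc50.json
hydratox report --in assay/ --extend --out report.json
```

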