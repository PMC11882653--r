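---
title: "Quantifying the fundamental niche of poikilohydric lichens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the fundamental niche of poikilohydric lichens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and its summary parameters

Lichens are poikilohydric: their water status passively tracks the
environment, and net CO2 exchange is a joint function of thallus water
content (WC) and irradiance. The measurement this package processes is a
*drying run*: a fully hydrated thallus is placed in a minicuvette at 18 °C
and 90% relative humidity, and a light-response curve (PPFD steps 0, 12,
25, 50, 100, 300, 500, 1000, 1500 µmol photons m⁻² s⁻¹) is recorded
repeatedly while the sample dries, with the thallus weighed before and
after every curve. Each curve is assigned the water content implied by the
mean of its bracketing masses (the *midpoint* convention; an *endpoint*
convention is available, and the two differ by at most
`(before − after) / (2·DM) · 100` percentage points).

From one drying run `hydroniche` extracts:

* **LCP, LSP** — the light compensation point (irradiance where net
  photosynthesis, NP, crosses zero) and light saturation point (lowest
  irradiance reaching 90% of the curve maximum), both linearly
  interpolated between the measured PPFD steps of the curve with the
  highest NP (the near-optimal-hydration curve).
* **MaxNP, DR, CGE** — maximum net photosynthesis over the run; dark
  respiration (the PPFD = 0 reading, reported as a positive magnitude);
  carbon gain efficiency `CGE = MaxNP / |DR at the MaxNP curve|`.
* **MinWC, MaxWC, OptWC** — the lower and upper water contents at which
  NP is 90% of MaxNP, linearly interpolated on the NP-vs-WC response at
  saturating light, and their difference, reported both as % of dry mass
  and as mm rainfall equivalent (1 mm ≡ 100 mg H2O cm⁻²;
  `wc_mm = wc_pct · STM / 10⁴` exactly). `OptWC = MaxWC − MinWC` holds
  exactly in both unit systems.
* **STM, WHC** — specific thallus mass `DM/area` (mg cm⁻²) and water
  holding capacity `(fully hydrated − DM)/(100·area)` (mm).
* **Chl** — chlorophyll a and a+b per mg DM from DMSO-extract absorbances
  at 665/649 nm, using a *named* coefficient set (`"arnon"` by default,
  `"barnes_dmso"` as the DMSO-specific recalibration) rather than
  anonymous constants.

Per-curve NP at saturating light is the **maximum over the steps at or
above the reference LSP** (a plateau estimate robust to per-step noise),
and the reference LSP is taken from the curve with the highest NP, in that
order. No smoothing is applied to any curve; every threshold crossing is a
linear interpolation between measured points, which keeps each estimator
transparent and testable. When the wettest (driest) measured point is
still above the 90% threshold the corresponding bound cannot be bracketed;
it is censored at the data range and flagged (`censored_high`,
`censored_low`) rather than set to `NA`, preserving downstream sample
sizes while recording the uncertainty.

A note on printed units: the source tables print NP per "g⁻² DM", a
dimensionally anomalous squared mass; throughout this package assimilation
is per gram dry mass (nmol g⁻¹ DM s⁻¹), and the anomaly is deliberately
not propagated. Similarly the printed chlorophyll unit "µg/mg DM⁻²" is
read as µg per mg DM.

## The synthetic protocol and its ground truth

Every downstream stage is testable without data downloads because the
package simulates the protocol with known ground truth. Noise-free model
NP at irradiance *I* and water content *w* (% of DM) is

    NP(I, w) = g(w) · A · tanh(φ·I/A) − rd(w)
    g(w)  = (1 − exp(−w/w_rise)) · exp(−max(0, w − w_supra)/w_decay)
    rd(w) = rd_max · w / (k_rd + w)

with `A = np_max_true`. The tanh light response is the minimal saturating
form consistent with the observed absence of photoinhibition up to 1500
PPFD; `g(w)` is the simplest unimodal hydration factor with separate
desiccation (`w_rise`) and suprasaturation (`w_supra` onset, `w_decay`
scale) limbs; respiration saturates with hydration. At `w = 0` the thallus
is dormant and NP is exactly zero. An optional resaturation-respiration
burst (elevated CO2 efflux on the wettest curve) is off by default: the
phenomenon is documented but has no established functional form.

`generate_drying_run()` descends from the sample's fully hydrated water
content to 2% of DM over `n_curves` curves — geometric spacing by default
(evaporation is fastest when wet), linear available for tests — adding
i.i.d. Gaussian noise with SD `noise_sd_frac · np_max_true` to every
assimilation reading. Masses are noise-free (balance precision far exceeds
flux noise) and exactly consistent with the curve-boundary water contents,
so the midpoint mass convention recovers the simulated WC without error.
The RNG is pinned (Mersenne-Twister, inversion) and every generator is
reproducible from a seed. `n_curves = 10` per run is a protocol-plausible
default; the source does not report the realised number of curves per
sample.

`true_core_parameters()` is the recovery oracle: the WC response at
saturating light is evaluated on a 0.1%-WC grid, the optimum refined by
golden-section search, the 90% bounds interpolated on the grid, and
LCP/LSP solved by root finding on the closed form at the optimal WC.

### Calibration to the published species panel

`reference_core_parameters()` transcribes the published species-level
means and SDs (n = 3, one species n = 2) of MaxWC, MinWC, OptWC (both
units), STM, WHC, MaxNP and CGE for the seven study species, ordered by
habitat-association rank. `calibrate_species_config()` inverts the
generative model per species: `stm_true`/`whc_true` are taken directly,
`φ = 2.5·A/1500` places light saturation in the observed 800–1100 PPFD
band, respiration is scaled so MaxNP/DR at the optimum matches the target
CGE, `w_decay` is tied to `0.5·w_supra`, and a Nelder-Mead search over
(`np_max_true`, `w_rise`, `w_supra`) matches MaxNP and the MinWC%/MaxWC%
targets (relative residuals below 1%). The published mm and % columns are
per-sample averages and are mutually inconsistent under any single STM at
the ~7% level (means of ratios are not ratios of means); calibration
targets the % columns, so mm ground truths agree with the printed mm means
only to that intrinsic level.

`fixture_panel()` perturbs the calibrated configuration per replicate with
**lognormal** multiplicative factors of mean 1 whose CV matches the
published SDs. Lognormal was chosen a priori because every perturbed
quantity is strictly positive with CVs up to ~0.42, where Gaussian draws
would produce negative masses and rates.

What the simulator does *not* emulate: resaturation bursts (unless
enabled), temperature responses (the protocol is isothermal), per-step
stabilisation dynamics, instrument drift, and within-thallus heterogeneity.
A green recovery test therefore establishes correctness of the estimators
against the stated generative world, not fidelity of that world to any
particular instrument.

## Statistical inference

The inference layer mirrors the published analysis and is implemented from
first principles, with base R distribution functions supplying reference
distributions and `MASS::polr`, `anova(lm())`, `cor.test` used only as
independent oracles in the test suite.

* **Normality screen** — Shapiro–Wilk on pooled within-group residuals;
  on rejection at 0.05 a `log` then `sqrt` transformation is tried and the
  first passing one kept (identity with a warning otherwise). Groups with
  n < 3 are excluded from the screen, mirroring the treatment of the n = 2
  species. Which transformation the original analysis applied per
  parameter is not stated, so exact F reproduction on real data may depend
  on this choice.
* **One-way ANOVA** — classical between/within decomposition;
  all-degenerate data yield an infinite-F sentinel rather than an error.
* **Tukey post-hoc with compact letter display** — Tukey–Kramer
  studentized-range pairwise tests, and letters by insert-and-absorb:
  starting from one letter covering all groups, each significant pair
  splits every letter containing both members, subsets are absorbed, and
  the result provably satisfies the defining property (groups share a
  letter exactly when not significantly different); the test suite
  brute-force checks this on random data. The post-hoc is gated on ANOVA
  significance, as in the source analysis.
* **Proportional-odds ordinal regression** — maximum likelihood for
  `P(Y ≤ j | x) = plogis(ζ_j − βx)` with thresholds parameterized as an
  initial value plus log-increments (monotonicity holds throughout
  optimization), BFGS with a polish pass, standard errors from the inverse
  observed information at the optimum, `t = β/SE`, and two-sided p from
  the standard normal. This reproduces the published p-values for the
  water-relations coefficients (e.g. t = 2.92 → p = 0.004) but not the
  internally inconsistent printed CGE line (t = −2.411 with p = 0.002; the
  normal reference gives 0.016) — the t statistic is reproduced and p is
  reported from the implemented reference distribution. Complete
  separation is detected structurally (category ranges perfectly ordered
  along x) and reported as a non-converged fit, never a silent number.
* **Habitat-association scan** — one univariate fit per core parameter,
  per-sample rows inheriting their species' rank (a species-means mode
  exists for sensitivity). No multiple-testing correction is applied
  across the nine scans, matching the source analysis; this is a
  documented property, not an oversight.

**A calibration caveat worth knowing.** With per-sample rows and
species-inherited ranks, the predictor is clustered by species, and the
Wald test's effective sample size is the number of species, not of
samples. In a permutation experiment on the calibrated panel, shuffling
ranks at the *sample* level (the exchangeable null) gives the nominal ~5%
false-positive rate, but shuffling at the *species* level — the null that
matches the inherited-rank design — gives ~28%. Identical t-values arise
from `MASS::polr`, so this is a property of the design, not the
implementation: per-sample univariate ordinal scans of species-level
predictors overstate significance.

## Realised-niche module

Occurrence cleaning applies, in order: missing-coordinate/year removal,
coordinate range checks, an inclusive 1979–2013 year window, exact
duplicate removal on (species, lat, lon, year), and an optional land-mask
predicate ("non-terrestrial coordinates" have no operational definition in
the source, so the mask is off by default). The audit counts sum to the
input row count and cleaning is idempotent. Climate values join by nearest
cell against a small in-memory lon/lat grid or a pre-extracted long table
(GeoTIFF input is not supported — no raster library is part of the
supported stack — and bulk GBIF/CHELSA retrieval is explicitly the user's
job); ties break deterministically toward the lower-indexed cell, and
records outside coverage are flagged, never dropped. Breadth summaries
report median, IQR and the 5–95% range per species, with a Spearman rank
correlation between habitat rank and breadth as the monotone-trend test.

## Numerical and design choices

* Units are fixed (mg, cm², µmol photons m⁻² s⁻¹, nmol g⁻¹ DM s⁻¹) with
  no autodetection; silent unit errors are the dominant hazard in this
  data type.
* Threshold fraction 0.9 for both LSP and the WC bounds, per the
  parameter definitions; configurable via `threshold`.
* Dark respiration is stored negative (assimilation sign convention) and
  reported as a magnitude in the core-parameter record.
* A noisily positive dark reading on the reference curve would make LCP
  undefined; extraction falls back to the highest-NP curve whose dark
  reading respires, and `lcp()` returns 0 (with a reason attribute) for a
  curve that compensates at zero light. Truly all-positive curves remain a
  hard validation error.
* The `--drop-first` option excludes the wettest curve to guard DR
  against resaturation-burst contamination; it is off by default because
  the burst is also off by default in the simulator.
* Whether the published per-sample analysis used the same curve for MaxNP
  and DR when forming CGE is ambiguous (the printed species means are not
  ratios of the printed MaxNP and DR means); this implementation uses the
  DR of the MaxNP curve, per sample.

## Known limitations

* With the protocol-like 10 curves per run, the 90%-threshold WC bounds
  carry an intrinsic interpolation error: the geometric drying schedule
  spaces adjacent curves ~1.7× apart in WC, and the plateau-max NP
  estimator is upward-biased under noise, which narrows the recovered
  optimum range. Median OptWC recovery error in the seeded acceptance
  experiment is ~21% (MaxNP ~4%); dense runs (30 curves) recover all WC
  bounds within 5%. Users wanting tight OptWC estimates should measure
  (or simulate) more curves per drying run.
* Exact reproduction of the published F statistics and ordinal
  coefficients requires the authors' per-sample data, which are not
  printed in the article; the package reproduces the analysis pipeline
  and its behaviour on calibrated synthetic panels.
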