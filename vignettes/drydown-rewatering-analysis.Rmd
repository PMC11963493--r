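---
title: "Methods: from raw drydown-rewatering measurements to mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw drydown-rewatering measurements to mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drydownr)
```

This vignette is the package's own account of its methods: what each stage
computes, the assumptions behind it, which parameters matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical choices made where convention is silent.

## The analysis problem

A drydown–rewatering experiment observes a small number of replicate potted
trees through three phases: progressive soil water depletion, rewetting, and
recovery. The measurements are heterogeneous: continuous 15-min sensor
series (meteorology, heat-pulse sap flow, stem water content), sampling-day
campaigns (leaf water potentials, soil volumetric water content at three
depths, soil and stem water isotopes, leaf gas exchange), and daily records
(shed leaf area). The scientific question addressed quantitatively is how
much each measurement constrains two kinds of target — plant water flux
(mean daily sap flow) and plant water status (predawn and midday leaf water
potential) — and how that constraint changes between the drydown and the
recovery, when physiological stress legacies can decouple variables that
were tightly coupled while water was limiting.

Mutual information is the dependence measure: it is non-parametric, captures
non-linear association, and is comparable across variable types. The price
is estimation at very small sample sizes, which drives most of the design
decisions below.

## Sensor cleaning

The cleaning pipeline for heat-pulse data is fixed, in this order:

1. **Negative-excursion removal.** Heat velocities below a threshold
   (default −5 cm h⁻¹) indicate sensor malfunction and are removed, never
   interpolated. The default is configurable because the threshold is a
   judgment about the instrument, not a statistical quantity; excursions of
   this kind are rare (on the order of 0.4% of points).
2. **Conversion to sap flux** by sapwood area (cm² → cm³ h⁻¹), with an
   optional scalar wound-correction factor (default 1).
3. **Hampel filtering.** Each point is compared with the median of a centred
   window (halfwidth 6 points = ±1.5 h at 15-min logging); points deviating
   by more than 3 × 1.4826 × MAD are replaced by the window median. The
   window tolerates diurnal curvature: on a linear ramp the maximum
   deviation is 6δ against a threshold of ≈13.3δ, so smooth signal is never
   touched, while isolated spikes are. At contamination rates around 14%
   the median and MAD retain enough breakdown margin that detection of
   large spikes stays near-perfect (verified against injected ground
   truth).
4. **Baseline correction** subtracts the minimum over valid points, taken to
   represent zero transpiration. Because the median and MAD are
   shift-equivariant, this step commutes with the Hampel decisions — a
   property the test suite asserts on random series.

Daily summaries apply one rule per variable: mean across depths (soil
moisture), daily means (VPD, irradiance, water potentials, gas exchange),
cumulative-to-date (leaf loss), mean during daylight (sap flow; daylight
defaults to irradiance > 10 W m⁻², with a fixed-clock alternative), and
daily 95th/5th nearest-rank percentiles (stem water content). Nearest-rank
is chosen because interpolation conventions differ across software and the
spec of record is silent; a daily cell requires 75% of expected points,
otherwise it is left missing. Sampling-day variables are missing — not
zero — on other days, and pairing for MI is pairwise-complete on the same
day.

## Soil water retention

Soil moisture is converted to water potential through the bimodal (Durner)
van Genuchten model

$$\theta(\psi) = \theta_r + (\theta_s - \theta_r)\sum_{i=1,2} w_i
\left[1 + (\alpha_i |\psi|)^{n_i}\right]^{-m_i},\qquad m_i = 1 - 1/n_i,$$

with pressure head in kPa internally (converters to MPa are provided since
plant physiologists report MPa). The Mualem constraint `m = 1 − 1/n` is
imposed because it is the near-universal convention for HYPROP/WP4C-type
laboratory retention data. Fitting is bounded Levenberg–Marquardt on θ
residuals (bounds: θr ∈ [0, 15]%, n ∈ (1, 10], α ∈ [10⁻⁴, 10] kPa⁻¹; α on a
log10 scale) with ten restarts — one data-driven, nine seeded random — and
best-RMSE selection; the two pore systems are reported coarse-first
(α₁ ≥ α₂) to remove label switching. Inversion ψ(θ) is bracketed
root-finding on log10|ψ| to a round-trip tolerance below 10⁻⁸ relative.
Residuals are taken on θ (not log|ψ|) because measurement error in these
instruments is approximately homoscedastic in water content.

## Isotope mixing and mean uptake depth

Isotopic abundances are handled in delta notation against VSMOW
(D/H = 155.76 × 10⁻⁶, ¹⁸O/¹⁶O = 2005.20 × 10⁻⁶). Mixing is delta-linear:
over the tracer ranges used here (hundreds of ‰) the error relative to
exact ratio-space mixing is below 0.1‰, far below the instrument precisions
(1.3‰ δD, 0.52‰ δ¹⁸O), and linearity keeps the inversion a quadratic
program.

Root uptake is assumed non-fractionating, so stem water is a mixture of its
soil sources. The uptake profile is estimated per tree and sampling day by

$$\min_f \; \lVert A f - b \rVert^2 + \lambda \lVert \Delta f \rVert^2
\quad\text{s.t.}\quad f \ge 0,\; \textstyle\sum_l f_l = 1,$$

where the columns of $A$ are the per-layer (δD, δ¹⁸O) pairs and $b$ the stem
pair, each isotope standardised by its measurement precision so the two
per-mil scales carry comparable weight, and $\Delta$ is the first-difference
operator across adjacent depths. The QP is solved exactly by enumerating
active sets of the non-negativity constraints (at most 2⁶ − 1 KKT systems
for a six-layer profile), so no iterative QP solver is needed and the
two-layer noise-free case inverts forward mixing to 10⁻⁶. λ defaults to an
L-curve corner search on a log-spaced grid.

Two practical points deserve emphasis:

- **Underdetermination and the reference profile.** With two isotopes and
  six layers the mixture is underdetermined; the penalty chooses which
  delta-consistent profile is reported. The plain first-difference penalty
  prefers uniform profiles, which biases the mean uptake depth toward the
  column midpoint whenever deep layers are isotopically similar — in
  synthetic recovery experiments this bias is ≈ +3.5 cm, uncomfortably close
  to the 5 cm accuracy one would like. When independent rooting information
  exists — root-mass profiles are routinely measured destructively in pot
  studies and decline roughly exponentially with depth for saplings — the
  penalty can smooth $f$ *relative to that shape* (`reference_profile`).
  `uptake_depth_table()` therefore defaults to an exponential root-mass
  reference with a 25 cm e-folding depth, which removes the flattening bias
  (recovery error ≈ 2 cm in synthetic tests) while leaving the data misfit
  essentially unchanged; `infer_uptake_profile()` itself defaults to the
  plain penalty so the unprioried estimator remains available.
- **Infeasible stem samples.** After rewatering flushes the soil with
  isotopically depleted water, stem water can remain more enriched than
  every soil layer — stored water from the drydown. Such samples cannot be
  expressed as any soil mixture; the nearest feasible point is reported with
  `feasible = FALSE` (the default flag threshold is a standardised misfit of
  3 combined precisions). The pipeline records these flags rather than
  dropping the samples, since the flag itself is scientifically informative.

Mean uptake depth is the fraction-weighted mean of layer mid-depths
(positive downward, 10-cm layers).

## Mutual information estimation

Entropies are plug-in (maximum-likelihood) in bits. MI is computed both as
$H(X) - H(X|Y)$ — with the conditional entropy accumulated stratum by
stratum — and as $H(X)+H(Y)-H(X,Y)$; the two routes must agree to 10⁻¹²,
which guards the implementation against bookkeeping errors. Only negative
values smaller than 10⁻¹² in magnitude are clipped to zero.

Discretization defaults to **2 quantile (median) bins**. The reasoning:
sampling-day variables have as few as five values over the experiment and
two or three per stratum-adjacent subset; more bins at such n produce
saturated, bias-dominated estimates. With two bins and log base 2, MI is
bounded by 1 bit, giving values a natural scale. Quantile binning also makes
MI invariant to monotone transforms of either variable, so units and
nonlinear calibrations do not matter. Constant series collapse to a single
bin (entropy 0) with a warning. No small-sample bias correction is applied
by default; the plug-in bias at (n, 2 × 2) is roughly $1/(2n\ln 2)$ bits and
affects all variable pairs alike within a stratum.

Periods: drydown = days before the rewatering day, recovery = the rewatering
day onward, full = all days. Pairing is same-day only — no lagged MI.

**Pooling.** Whether replicate trees should be averaged before estimating MI
is a genuine open choice. The package defaults to pooling (tree, day) pairs
as samples, for a statistical reason: the recovery stratum contains only two
sampling days, and MI between two across-tree daily means is degenerate
(exactly 1 bit whenever both variables differ between the two days, 0
otherwise). Pooling trees gives 12–18 samples per stratum and non-degenerate
estimates; it treats trees as exchangeable replicates, which the experiment
design intends. The across-tree-mean mode (`pooling = "mean"`) is provided
for sensitivity analysis.

## The synthetic experiment generator

The generator exists so that every downstream stage can be verified against
known ground truth; it is a statistical emulator, not a process model. Its
components:

- **Soil**: six 10-cm bucket layers per tree (60 cm column, 40 cm pot
  diameter). Uptake per layer is proportional to root fraction (exponential
  decline, 25 cm e-folding) times layer wetness; the top layer loses a small
  evaporation flux. Layer water potential comes from the same bimodal
  retention model the analysis uses.
- **Watering events** (day-0 surface ¹⁸O tracer ≈ 100‰, day-0 deep δD
  tracer ≈ 350‰ injected at 28–30 cm, day-10 tap-water rewatering at
  −12.2‰ δ¹⁸O / −88‰ δD followed by a surface δD tracer) infiltrate as
  mixing piston displacement: incoming water mixes into a layer and the
  excess above field capacity is displaced downward at the mixed
  composition; water displaced below the column drains out of the pot and is
  tracked. This produces the observed tracer layering — a surface-enriched
  δ¹⁸O gradient, a mid-column δD peak, and after rewatering a flushed,
  depleted profile with δD-tagged upper layers.
- **Stem storage** is a finite capacitor (3.5 L default — a few litres is
  the right order for 2–3 m saplings) refilled down a root-to-storage
  potential gradient; transpiration is drawn from it. Its isotope pool mixes
  with a finite residence time, so after rewatering with low flow the stem
  retains drydown-enriched water — reproducing stem samples more enriched in
  δ¹⁸O than any soil source on the first post-rewatering sampling day. The
  mean uptake depth of the water in the stem is carried as an additional
  conservative tracer, which is the correct truth for what a stem sample can
  encode once storage mixing is accounted for.
- **Stress legacy**: a stomatal factor s ∈ [0, 1] decays while root-zone
  potential is beyond an onset (−0.7 MPa) and relaxes toward 1 after
  rewetting with a time constant τ (mean 7 days, lognormal across trees
  with CV 0.8, so day-12 flow is a minimal increase and day-15 recovery
  ranges from partial to nearly complete across trees). The across-tree spread of τ is what decouples
  recovery-period sap flow from the uniformly rewetted soil — the
  qualitative signature the generator must reproduce — while τ → 0 recovers
  the memory-free limit. Leaf loss is a saturating function of integrated
  stress, calibrated so total loss lands in a 30–60% band; it is permanent,
  so flux "recovery" is partial even without stomatal memory.
- **Heterogeneity**: per-tree lognormal spread of canopy conductance (CV
  0.15), sapwood area (CV 0.1), the legacy time constant, and a per-pot
  offset (SD 2.5% vol) on initial/field-capacity water content emulating
  packing differences — replicate pots in practice show broadly overlapping
  soil moisture ranges on any given day.
- **Observation model**: Gaussian sensor noise, isolated positive spikes
  (14% of points, amplitudes 5–15 robust SD — negative-going impulses are
  physically the excursion class and are injected separately at 0.4% with
  values −60 to −20 cm h⁻¹), isotope noise at instrument precisions, probe
  noise on soil moisture and water potentials. Artifact masks are returned
  as ground truth.

Meteorology is sinusoidal-diurnal with day-to-day jitter confined to
realistic ranges (daily T highs 18–25 °C, lows 12–15 °C; VPD maxima
0.75–1.75 kPa, minima 0.2–0.3 kPa; midday irradiance near 1000 W m⁻²), with
RH derived so VPD, T and RH are exactly consistent under the package's
saturation formula.

Water and heavy-isotope mass balances close to machine precision at every
step by construction, and the per-step residuals are part of the returned
truth so tests assert them rather than trust them.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: Richards-equation soil physics and hysteresis;
evaporative isotope fractionation at the soil surface (the enriched surface
layer comes from the tracer, not from modelled fractionation); xylem
embolism and hydraulic damage; carbon metabolism; instrument drift and
diurnal error structure; and any root uptake fractionation. Conclusions
about estimator behaviour under those processes require real data.

```{r example, eval = FALSE}
cfg <- pipeline_config(synthetic = experiment_config(seed = 1L), seed = 1L)
res <- run_pipeline(cfg, "out")
subset(res$mi, measurement == "soil_moisture" & target == "sap_flow")
```

## Numerical choices and degenerate inputs

- Retention inversion brackets log10|ψ| in [−12, 12] (extended if needed)
  with uniroot tolerance 10⁻¹³; θ = θs maps exactly to ψ = 0; θ outside
  (θr, θs] is a domain error naming the bounds.
- The mixing QP enumerates non-negativity active sets; singular KKT systems
  (possible at λ = 0 with collinear layers) fall back to a 10⁻¹⁰ ridge and
  are skipped if still singular — the optimum's own active set always
  remains among the solvable candidates.
- MI with fewer than three complete pairs is returned flagged unreliable,
  not as an error, because short strata are a fact of sampling-day designs;
  an empty stratum produces no rows at all.
- Ties in quantile binning are resolved rank-then-input-index; a constant
  series is a single bin with a warning.
- `rewater_day` may equal `n_days`, meaning the experiment ends before
  rewatering; the recovery stratum is then empty and its MI rows are absent.
- All simulation state updates are written as explicit mass bookkeeping so
  the balance residual is a genuine check, not a tautology: inflow, uptake,
  transpiration, evaporation and drainage are accumulated independently of
  the state update they describe.

## Verification strategy and problem sizes

The test suite checks every stage against an independent oracle: brute-force
double-sum MI on exhaustively enumerated joint tables (all ≤ 3 × 3 tables
with total count ≤ 12), the dichotomized-Gaussian closed form
(p_same = ½ + arcsin ρ/π at n = 10⁵), closed-form unimodal retention against
the bimodal w₁ → 1 limit, per-window Hampel recomputation on series up to
200 points, forward-then-invert mixing oracles, and 20-seed recovery
experiments for retention parameters, uptake depth (tolerance 5 cm), spike
detection (≥ 95%) and the drydown-versus-recovery MI ordering (≥ 80% of
seeds). Twenty replicate experiments of 6 trees × 16 days at 15-min
resolution keep the full suite within a few minutes on one CPU while leaving
the binomial uncertainty of the seed-fraction checks well below their
margins. The same quantities are recomputed end-to-end by
`scripts/acceptance.R`.

## Known limitations

- The MI estimator settings (bins, base, pooling, bias correction) dominate
  small-sample MI values; numerical MI values are comparable only within a
  fixed configuration. The defaults are surfaced in `pipeline_config()` and
  echoed into the run report precisely because of this.
- The uptake inversion reports one delta-consistent profile; with two
  isotopes the full profile is not identifiable, and only functionals like
  the mean depth — stabilised by the reference shape — should be
  interpreted.
- Delta-linear mixing, non-fractionating evaporation in the generator, and
  the bucket infiltration scheme are deliberate simplifications; they bound
  the realism of synthetic validation, not the correctness of the
  estimators.
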