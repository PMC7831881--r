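---
title: "Quantifying cardiorespiratory pausing under warming and CO2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiorespiratory pausing under warming and CO2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pauseflow)
```

## The physiological problem

Resting decapod crustaceans do not hold a steady metabolic rate. Edible
crabs alternate between short, pronounced pulses of oxygen consumption and
phases of near-zero metabolic, ventilatory and cardiac activity — "pausing
behaviour". At a control temperature of 12 °C an undisturbed crab shows
roughly 1–3 metabolic pulses per hour: a fast rise to a maximum lasting a
few minutes, a slower (~10 min) decline back to a low baseline, and a
(~10 min) pause during which ventilation nearly stops, the heart slows to a
few beats per minute, and whole-animal oxygen consumption approaches zero.
Warming shortens the pauses and raises the pulse maxima; elevated seawater
CO2 (hypercapnia, ~1,350 µatm) keeps the pauses long even at the warm end
of the range, so the animal spends nearly twice as much time in a
hypometabolic state.

`pauseflow` implements the full computational chain needed to quantify this
behaviour from non-invasive recordings:

1. a seeded **synthetic-recording generator** (activity profiles, paired
   optode traces through a mixed flow-through chamber, infra-red
   photoplethysmography (IR-PPG) pulse trains, vessel flow-velocity
   records) so every downstream stage is testable without any deposited
   raw data;
2. **flow-through respirometry**: MO2 = ΔP~w~O2 · α~O2~ · FR / w~f~, with
   inlet–outlet delay correction;
3. the **IR-PPG chain**: smoothing, SD-threshold beat detection, per-minute
   heart rate, a stroke-volume proxy from the per-minute signal integral,
   normalisation to an absolute stroke volume, and cardiac output;
4. the **quartile-occupancy pausing statistic** with robust outlier
   screening and exclusion of spontaneously elevated activity;
5. a **seawater carbonate-system solver** for the measured (pCO2, pH)
   input pair;
6. the **inference layer**: animal-random-intercept mixed models,
   Tukey-HSD contrasts, Kruskal–Wallis with a Tamhane T2 post hoc,
   and Wilcoxon rank-sum tests.

## The synthetic generator and its calibration

The generator is first-class, tested code, and its defaults *are* the study
conditions. Each cycle draws phase durations from a lognormal jitter
distribution (CV 0.2) around the nominal durations, a pulse amplitude
uniformly from 92–100 % of the condition's ceiling, and a slowly wandering
inter-pulse baseline (lognormal, CV 0.12). The decline is exponential
towards the baseline and fills the cycle time not used by rise, peak and
pause. Heart rate, ventilation, perfusion and stroke volume co-fluctuate
with the metabolic cycle through a common activity index, so pauses are
accompanied by bradycardia and hypoventilation, and the flow table makes
ventilation unilateral during pauses (one body side exactly zero).

```{r profile}
prof <- make_activity_profile(default_params(12, "normocapnia"),
                              duration_h = 10, seed = 1)
round(prop.table(table(prof$phase_label)), 2)
```

Numeric anchors that the defaults are calibrated to, at 1-min sampling over
20 h records:

* 2 pulses per hour at 12 °C (range 1–3 across jittered records), pulse
  maxima lasting well under 10 min, declines of ~10 min, pauses of ~10 min
  at 12 °C;
* the fraction of time in the **lowest quarter** of the per-record MO2
  range is ~40 % at 12 °C, falling toward ~20 % at 20 °C under
  normocapnia, while hypercapnic records stay at 30–50 % at all
  temperatures (about twice the normocapnic value at 18–20 °C);
* the fraction of time in the **top quarter** is ~15 % in every condition;
* hypercapnic pulse maxima reach 75 nmol min^-1^ g^-1^ already at 12 °C;
  normocapnic maxima rise with warming to a plateau of 56 nmol min^-1^
  g^-1^; zero-level pauses disappear above 18 °C under normocapnia.

The waveform geometry (peak durations of 1.8–3.5 min, baseline levels,
amplitude ceilings, metabolic channel noise SD of 1.2 nmol min^-1^ g^-1^)
was fixed once so the noiseless occupancy geometry plus boundary noise
reproduces these fractions, and is not meant to be tuned per analysis. Two
non-obvious choices deserve a note:

* *Baseline wander.* Without slow baseline drift the simulated bulk
  distribution at the warm end is so tight that the robust outlier screen
  (modified Z ≥ 3.5) flags every short metabolic pulse wholesale, which
  real records do not show — the screen exists to remove stray sensor
  points, not the pulses themselves. A CV-0.12 wander restores a realistic
  bulk spread.
* *Normocapnic amplitude plateau.* The 75 nmol min^-1^ g^-1^ ceiling is a
  hypercapnia observation at 12 °C; normocapnic maxima plateau at 56 in
  the defaults, which both respects the reported monotone rise and keeps
  the peak-to-bulk amplitude ratio below the modified-Z flagging point.

What the generator does **not** emulate: activity-dependent changes in
pulse shape, diurnal rhythms, sensor drift and dropouts, movement
artefacts in the PPG, or the spatial structure of MRI flow measurements
(vessel records are emitted directly as ROI-equivalent tables; imaging is
out of scope). Passing tests on synthetic data therefore demonstrate that
the analysis chain recovers known truth under the stated statistical
structure, not that it is robust to every failure mode of real recordings.
Spontaneously elevated activity episodes are generated at a default
Poisson rate of 0.05 h^-1^ (≥ 2 h each); the reported episodes' frequency
and amplitude are not quantified in the source material, so this default
is a placeholder, not an empirical claim.

## Respirometry

Oxygen consumption follows the flow-through equation; the solubility
coefficient α~O2~ (µM torr^-1^) comes from the Benson–Krause data as refit
by Garcia and Gordon, converted to per-litre units with the one-atmosphere
seawater equation of state, and percent-air-saturation readings convert to
torr with a 0.2094 O2 mole fraction and a Buck water-vapour correction
(barometric pressure defaults to 760 torr with a warning when metadata are
absent).

```{r mo2}
oxygen_solubility(12, 33)
```

The chamber imposes a first-order mixing kernel between the animal and the
outlet optode. The discrete kernel pole is placed at τ/(τ+Δt) so the
impulse response's first-moment lag equals the nominal 3–4 min delay
exactly and the DC gain is exactly one (mass conservation; the time
integral of inferred consumption equals the integral of true consumption).
Two corrections are available in `compute_mo2()`:

* `delay` alone applies a pure integer-sample advance of the outflow (the
  default behaviour); trailing samples without support become `NA`, never
  extrapolated. This synchronises the series but cannot undo the smearing
  of fast transients.
* `deconvolve = TRUE` inverts the single-compartment kernel exactly
  (x~t~ = (y~t~ − a·y~t−1~)/(1−a)). On noiseless synthetic pairs the
  round-trip error is at machine precision; on noisy data deconvolution
  amplifies optode noise by roughly (1+a)/(1−a), so the pipeline pairs it
  with the low noise levels typical of temperature-compensated optodes.

Negative MO2 transients caused by sensor noise are retained and flagged
rather than clipped: clipping would bias the minimum of the range on which
the occupancy quartiles are built.

## The PPG chain

Raw voltage traces are smoothed (0.1 s moving average) and excursions
below a 0.02 V noise floor are flattened against the per-minute baseline.
Beats are positive local maxima at least k standard deviations above the
signal mean, with both statistics computed per minute so drifting
baselines do not leak into the threshold; k lives in the reported 1.5–3.4
range and `k = "auto"` selects the smallest k (0.1 steps) minimising the
inter-beat-interval CV, a regularity criterion that needs no ground truth.
A 0.3 s refractory period (max credible 200 beats min^-1^) suppresses
double counts. Heart rate is the beat count in left-closed right-open
1-min bins.

The stroke-volume proxy is the midpoint-rule integral of the *raw* signal
above the minute's absolute minimum, divided by the minute's beat count —
per-beat units are required for CO = HR · SV to be dimensionally
consistent (the alternative per-minute normalisation is exposed through
the arguments, per-beat is the default interpretation). SVP in V s is then
scaled so its mean over a 12 °C reference window equals 0.2 ml per beat,
separately per CO2 treatment, which removes sensor-placement effects on
absolute signal size; after this step HR, SV and CO are invariant to any
positive rescaling of the raw voltage.

```{r ppg}
prof <- make_activity_profile(default_params(12, "normocapnia"),
                              duration_h = 10 / 60, seed = 2)
trace <- make_ppg_trace(prof, sampling_rate = 100, seed = 3)
head(analyze_ppg(trace, reference_mask = 1:10), 3)
```

## Pausing statistics

For one animal × temperature × CO2 combination, the retained MO2 samples
(after modified-Z outlier screening, exclusion of elevated phases, and
restriction to the last hours of the temperature step) define a total
range; `frac_low` and `frac_high` are the fractions of samples in the
lowest and highest quarter of that range. The range is computed *after*
outlier removal and exclusion so single stray samples cannot stretch the
quartile thresholds. Records whose range is smaller than ten times the
median absolute successive difference are rejected as degenerate,
mirroring the exclusion of constant-performance animals. Occupancy is
invariant to affine rescaling of the input.

Elevated phases are detected as spans where the 60-min rolling minimum
stays above the range midpoint; because the rolling minimum erodes an
episode by half a window at each end, the detected core is dilated back by
the half-window before the ≥ 2 h duration rule is applied. Episodes are
judged on the whole plateau record before the analysis window is cut, and
when an episode consumes the window entirely the pipeline falls back to
all fluctuating activity of the plateau.

Pulse counting accepts local maxima with a prominence of at least half the
range, separated by ≥ 10 min, and normalises by record length.

## Carbonate chemistry

`solve_carbonate()` computes CO2*, bicarbonate, carbonate, DIC and total
alkalinity from the measured (pCO2, pH) pair with K0 (Weiss), K1/K2
(Mehrbach data refit by Dickson & Millero, seawater scale), KB (Dickson),
KW (Millero), KSO4 (Dickson) and Uppström total boron. Phosphate and
silicate alkalinity are zero (not measured); pressure is surface; fluoride
is omitted from the scale conversion, sulfate being the dominant
correction term.

One genuinely open choice is the pH scale the original per-sample CO2SYS
computations used: the printed computed columns are mutually consistent
only if the tabulated pH is paired directly with the seawater-scale
constants. With that pairing (the `ph_scale = "sws"` default), the
normocapnic 12 °C water column solves to DIC 2.647, HCO3^-^ 2.448 and TA
2.873 mmol kg^-1^ — within 1 % of the printed means — whereas a strict
free→SWS conversion lands ~13 % low on all three. The scale is therefore
an explicit argument, and re-solving the system from the computed (TA,
DIC) pair recovers the inputs to 0.1 % (closure), so the solver is
internally consistent under either convention.

```{r carbonate}
solve_carbonate(pco2 = 478, ph = 8.06, temperature = 11.85,
                salinity = 32.75)
```

## Inference layer

Responses are standardized, then modelled as
`value ~ temperature * co2_level + (1 | animal_id)` with `lme4`: the
random intercept absorbs repeated measurements and inter-individual
baselines; random slopes are deliberately unsupported (they were omitted
to avoid overfitting at small animal numbers). Variance components are
estimated by REML; the likelihood-ratio test of the interaction refits
both models with ML. Cell-mean contrasts use `emmeans` with the
studentized-range (Tukey) family correction; the degrees-of-freedom
method is whatever `emmeans` reports in its output rather than a guess at
the original software's choice. Occupancy fractions — bounded, non-normal,
few animals — are compared with rank statistics implemented in the
package: a tie-corrected Kruskal–Wallis H with exact enumeration of all
rank assignments for total n ≤ 8, a Tamhane T2 post hoc (pairwise Welch
t with a Šidák-style conservative family adjustment), and a Wilcoxon
rank-sum with exact p for total n ≤ 10 without ties. Mid-ranks with
tie-corrected variances are used throughout.

## Numerical choices and degenerate inputs

* All randomness flows through one seeded Mersenne-Twister generator per
  call; the caller's RNG state is saved and restored, so identical
  (parameters, seed) give bitwise-identical outputs and no global state
  leaks.
* Jittered phase durations that would overflow their cycle are rescaled
  proportionally into 90 % of the period rather than rejected, keeping
  the mean cycle rate at its nominal value.
* A zero MAD in the outlier screen falls back to the mean absolute
  deviation (consistency factor 0.7979) with a warning.
* `detect_beats` on a constant trace returns zero beats (no strict local
  maxima, zero SD); minutes without beats give missing SVP/SV/CO, and
  missingness propagates through products.
* The exact Kruskal–Wallis enumeration is O(n!) and therefore capped at
  n = 8 (40,320 permutations); beyond that the tie-corrected chi-square
  approximation is used.
* `run_experiment` derives one sub-seed per animal × CO2 × temperature
  combination from the design seed, so bundles are reproducible and
  individual runs can be replayed in isolation.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script size their simulations as
follows: occupancy checks use 20 h records (1,200 samples) over 5 seeds at
12 °C plus 3 seeds per condition cell for the pooled top-quartile check;
heart-rate recovery uses four rates × 10 min at 100 Hz; the mixed-model
recovery study uses 100 replicates of 8 animals × 5 temperature steps ×
200 observations; the end-to-end experiment test uses 4 animals × 3
temperature steps × 6 h plateaus under both CO2 levels. These sizes give
stable estimates (SD of the occupancy means ≈ 0.5–1 percentage point
across seed sets) for the tolerances being checked.

## Known limitations

* The SVP → SV normalisation fixes only the reference-window mean;
  absolute SV outside the reference conditions inherits any nonlinearity
  between the optical signal integral and true stroke volume.
* Deconvolution assumes a single well-mixed compartment; real chambers
  with dead zones would need a higher-order kernel.
* The carbonate solver is deliberately not a general CO2SYS replacement:
  only the (pCO2, pH) input pair is first-class; the (TA, DIC) inverse
  exists for consistency checking.
* Exact rank-test enumeration is limited to the tiny samples where it is
  feasible; all larger cases rely on standard asymptotics.
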