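---
title: "Transfer function analysis of dynamic cerebral autoregulation with dcar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer function analysis of dynamic cerebral autoregulation with dcar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcar)
```

## The physiological problem

Dynamic cerebral autoregulation is the fast-acting cerebrovascular response
that buffers cerebral blood flow against spontaneous fluctuations in
arterial pressure. It is commonly quantified without any provocation by
treating the cerebral circulation as a linear system: spontaneous
oscillations in mean arterial pressure (MAP, mmHg) are the input, and
middle cerebral artery blood flow velocity (MCAv, cm/s, from transcranial
Doppler) is the output. Three frequency-domain quantities summarise the
system in each analysis band:

* **transfer gain** `|S_xy(f)| / S_xx(f)` (cm s⁻¹ mmHg⁻¹) — how much of a
  pressure oscillation reaches the flow velocity; lower gain means better
  buffering;
* **normalised gain** `gain × mean(MAP) / mean(MCAv)` — the same quantity
  in percent-per-percent units, removing the dependence on absolute
  levels;
* **phase difference** `Arg(S_xy(f))` (rad) — with the convention used
  throughout this package that *positive phase means MCAv leads MAP*.
  Autoregulation behaves like a high-pass filter, so healthy subjects show
  a positive low-frequency phase; a *larger* phase or a *smaller* gain is
  read as *enhanced* autoregulation, and vice versa
  (`interpret_direction()` reports these verdicts per metric and never
  fuses them).

**Squared coherence** `|S_xy|² / (S_xx S_yy)` plays the role of a
per-frequency R²: where it is low, gain and phase are not interpretable.
Band estimates whose coherence falls below 0.4 are flagged invalid, and a
subject with an invalid low-frequency band in any recording is excluded
from the autoregulation summaries (but kept in the oxygen-reactivity
analysis, where only steady-state means are needed).

## The estimation procedure

`analyze_recording()` chains the stages that `run_study()` applies to every
recording:

1. **Windowing** — the trailing 600 s of each intervention
   (`extract_analysis_window()`), by which time the physiological state is
   stationary.
2. **Resampling to 10 Hz** (`resample_to_analysis_rate()`). The
   anti-alias filter is a zero-phase FFT-domain low-pass: unit gain up to
   1.5 Hz, raised-cosine roll-off, zero beyond 2.5 Hz, followed by
   interpolation onto the 10 Hz grid. Zero phase is the deliberate design
   choice here — the phase difference is the headline quantity and any
   causal filter would bias it. The filter band sits far above the 0.30 Hz
   top of the analysis range, so in-band amplitude distortion is below
   1%, while anything that could alias into the analysis bands is removed
   entirely. Upsampling is refused rather than interpolated: fabricated
   samples would manufacture spurious coherence.
3. **Welch cross-spectral estimation** (`welch_cross_spectra()`):
   1200-sample segments (120 s at 10 Hz), 60 s overlap between successive
   segments (50%), per-segment mean removal, Hanning taper, one-sided
   densities with the standard `2/(fs · Σw²)` window-power correction. A
   600 s window yields 9 segments. Per-segment *mean removal only* (no
   linear detrending) is used — standard Welch practice; the trailing
   window is taken specifically because the signals are stationary there.
4. **Band averaging** (`band_average()`): VLF 0.02–0.07 Hz, LF
   0.07–0.20 Hz, HF 0.20–0.30 Hz. Gain, phase and coherence are averaged
   bin-wise over the band (not recomputed from band-averaged spectra —
   the mainstream convention in cerebral-autoregulation work; at the
   default resolution of 1/120 Hz the LF band holds 15 bins). Band powers
   `MAP_sp` and `MCAv_sp` are PSD integrals over the band (mmHg², cm² s⁻²).
   Bin inclusion uses half-open intervals `[f_lo, f_hi)` with the HF band
   closed at 0.30 Hz, so shared edges are never double-counted. The phase
   is the principal value of the cross-spectral argument; no unwrapping is
   attempted because physiological phases at these frequencies stay well
   inside (−π, π].

LF is the primary autoregulation band: respiratory contamination of MAP is
minimal there, and the Mayer waves near 0.1 Hz provide the input power.

### Numerical choices and degenerate inputs

* Bins with zero MAP power are reported as `NA`, not infinity.
* Coherence from a single segment is identically 1 and carries no
  information; it is returned as `NA` with a warning.
* The coherence validity rule is a `>=` comparison: a band coherence of
  exactly 0.40 is valid, 0.28 is not.
* Constant channels produce identically zero spectra after mean removal.
* Recordings with gaps or missing samples are rejected at ingest; gap
  imputation would silently bias phase, so it is deliberately not offered.

## The synthetic-data generator

No public repository of raw pressure/velocity recordings from
endotoxaemia studies exists, so the package carries a first-class
generator (`simulate_map()`, `simulate_mcav()`, `simulate_cohort()`) whose
defaults encode the study conditions the analysis targets:

* **MAP model** — setpoint 88 mmHg plus three sinusoids (0.05 Hz / 2 mmHg,
  a Mayer component at 0.10 Hz / 3 mmHg, a respiratory component at
  0.25 Hz / 2 mmHg) plus 1 mmHg broadband Gaussian noise. This is the
  minimal structure that puts power into all three analysis bands; the
  Mayer amplitude of 3 mmHg makes the LF band-integrated MAP power
  A²/2 = 4.5 mmHg², the order of magnitude reported for resting
  volunteers. No quantitative MAP spectrum was available to fit, so these
  amplitudes are order-of-magnitude choices, made once.
* **MCAv model** — a linear time-invariant system applied in the frequency
  domain (`transfer_model()`): identity, flat gain, pure delay, or a
  frequency template interpolated linearly between nodes. The
  cohort generator uses `band_transfer_template()`, a template whose gain
  and phase are *constant across each band* with narrow transitions placed
  between the bands' edge bins: every in-band Welch bin sits on a plateau,
  so the band-averaged ground truth equals the plateau value exactly and
  recovery tests are sharp. Defaults follow the high-pass autoregulation
  pattern (LF gain 1.26 cm s⁻¹ mmHg⁻¹, LF phase 0.58 rad at baseline,
  VLF phase higher, HF phase lower, gain rising with frequency).
* **Noise and coherence** — independent Gaussian noise is added to the
  MCAv channel only, *after* filtering. This single mechanism controls
  coherence and gives the closed form
  `C(f) = S_signal / (S_signal + S_noise)` with
  `S_noise = 2σ²/fs`, which the tests verify against the estimator. The
  default σ = 0.5 cm/s puts LF coherence near 0.9, matching healthy
  recordings. (At much heavier noise the Welch coherence estimator's
  positive bias of order `(1−C)²/K_eff` becomes visible; the closed-form
  check is therefore run at the default noise level, where the bias is
  ≲ 0.003.)
* **Condition effect** — the inflammatory condition raises every subject's
  LF phase plateau from a cohort median of 0.58 rad to 0.82 rad while
  leaving gain unchanged. Subject offsets (SD 0.19 rad, consistent with
  the interquartile spread of reported LF phases) are drawn once per
  subject and shared by both conditions, making the design genuinely
  paired.
* **Blood gases and vasoreactivity** — per-intervention targets for PaO2
  (13.2 / 28.5 / 7.5 kPa at baseline; 11.6 / 26.7 / 7.1 kPa after the
  condition), SaO2 and PaCO2 follow typical values for FiO2 21% / 40% /
  12%; haemoglobin targets (8.44 / 8.35 mM) are *synthetic*, back-solved
  so that `compute_cao2()` reproduces arterial oxygen contents near
  8.4 mM. Per-intervention MCAv setpoints are derived from subject-level
  signed vasoreactivity slopes (baseline: −0.7 %/kPa hyperoxic,
  −1.1 %/kPa hypoxic; post-condition: −0.2 and −2.1) applied to the
  realised PaO2 differences, so `compute_covr()` recovers the configured
  slopes.

### Seeding contract

Everything is reproducible bitwise from integer seeds.
`simulate_cohort()` seeds at two levels: the effect config's seed fixes
the *subject-level truth* (parameter offsets and blood-gas panels), while
a separate realisation seed drives only the recording noise. Two
realisation seeds therefore give different signals with identical
ground-truth metadata, and the truth is returned alongside the data (and
written to a `truth.yaml` sidecar by `write_cohort()`) so recovery tests
read it rather than re-derive it.

### What the generator does and does not emulate

The generator produces stationary, strictly linear recordings with purely
additive output noise. Real recordings have pulsatile beat-to-beat
waveforms, nonstationary drifts, breathing-rate wander, CO₂-mediated
feedback and hysteretic (direction-dependent) autoregulation — none of
which are modelled. Passing the recovery tests therefore demonstrates
that the *estimator chain is correct for the linear model class it
assumes*, not that real cerebral haemodynamics are linear. That caveat is
inherent to transfer function analysis itself.

## Oxygen content and vasoreactivity

`compute_cao2()` implements
`CaO2 (mM) = SaO2 (fraction) × Hb (mM) + 0.01 × PaO2 (kPa)`.
Cerebral oxygen vasoreactivity (`compute_covr()`) is the percent change
in MCAv per kPa change in PaO2, with the same-condition normoxic
intervention as the reference and steady-state levels taken as trailing
four-minute means (`segment_mean()`). Hyperoxia and hypoxia are assessed
separately because the flow–oxygen relation is nonlinear. The slope is
stored *signed* (ΔMCAv% / ΔPaO2, so both challenge directions give
negative slopes in a healthy subject); the customary verbal form
("x % increase in MCAv per kPa decrease in PaO2") is rendered only in
`reported_magnitude`, because magnitude-with-direction phrasing is
ambiguous for downstream arithmetic. Cohort vasoreactivity is summarised
as the median of per-subject slopes — never as a ratio of medians. The
CaO2-based variant (`compute_covr_cao2()`) substitutes oxygen content
(per mM) for tension.

## Cohort statistics

Cerebral haemodynamic quantities are not normally distributed in small
cohorts, so the pipeline uses paired nonparametric inference throughout:

* `wilcoxon_signed_rank()` — exact permutation null (all 2ⁿ sign
  assignments, computed by dynamic programming over doubled mid-ranks, so
  ties are handled exactly) for n ≤ 20; zero differences are dropped
  before ranking (Wilcoxon's original convention — documented and
  configurable via the inputs); two-sided p doubles the smaller tail. A
  tie- and continuity-corrected normal approximation takes over only
  beyond n = 20, far above the cohort sizes this design targets.
* `holm_adjust()` — Holm's step-down correction, applied *within each
  comparison family per band and metric*: the four
  intervention-vs-normoxia comparisons form one family and the three
  across-condition comparisons another. The family structure is a design
  choice (the natural reading of "adjusted for multiple comparisons"
  over a fixed comparison set) and is visible in the `family` column of
  the comparisons table.
* `median_iqr()` — median and quartiles by linear interpolation between
  order statistics (type-7 quantiles), the documented convention for all
  summaries.

A linear-mixed-model analysis of time-course variables is out of scope:
it is an off-the-shelf fit with no bespoke methodology, and the
transfer-function, vasoreactivity and paired nonparametric machinery is
what this package exists to provide.

## Worked example

```{r example, eval = FALSE}
effect <- cohort_effect_config(n_subjects = 10, seed = 1)
cohort <- simulate_cohort(effect)
result <- run_study(cohort)

subset(result$tfa_summary,
       band == "LF" & metric == "phase" & intervention == "normoxia")
subset(result$comparisons,
       band == "LF" & metric == "phase" & family == "lps_vs_baseline")
render_tables(result, "results/tables")
```

The same analysis is available from a shell via the `exec/dcar` script
(`dcar simulate`, `dcar tfa`, `dcar covr`, `dcar study`).

## Validation strategy and problem sizes

The test-suite checks are oracle- and property-based, at these problem
sizes (chosen once as the smallest sizes at which each property is
informative):

* single-segment Welch output against a brute-force O(N²) DFT
  periodogram, bin by bin, at numerical precision;
* noiseless identity / flat-gain / pure-delay / template systems
  recovered within 2% gain and 0.05 rad phase from 600 s of 10 Hz data
  (9 segments);
* coherence bounded in [0, 1] on 1000 random fixtures, and equal to the
  closed-form `S/(S+N)` within 0.05 averaged over 20 seeds at the default
  noise level;
* exact Wilcoxon p equal to full 2ⁿ enumeration for n ≤ 12; Holm equal to
  longhand step-down and bounded between no correction and Bonferroni;
  empirical size of the paired LF-phase test within 5% ± 2% over 1000
  null cohorts (10 subjects, zero condition effect, 600 s recordings);
* CaO2 and vasoreactivity hand-arithmetic cases to three decimals;
* end-to-end recovery over 200 replicate 10-subject studies (600 s
  recordings, default moderate noise): cohort median LF phases within
  0.05 rad of the realised ground-truth medians and the condition effect
  declared significant (Holm-adjusted p < 0.05) in at least 80% of
  replicates — in practice the exact paired test at n = 10 gives
  p = 0.0059 whenever all ten paired differences are positive, which the
  0.24 rad effect all but guarantees;
* the exclusion rule: one corrupted low-coherence cell removes exactly
  that subject from the autoregulation summaries while keeping it in the
  vasoreactivity tables, with the reason logged.

Replicate loops simulate 600 s recordings directly (the analysis window
itself); single-study examples and `scripts/acceptance.R` use full
20-minute recordings so the windowing stage is exercised too.

## Known limitations

* Strictly linear, stationary generator — see above; no beat-level
  waveforms, no baroreflex or CO₂ feedback, no hysteresis.
* Band aggregation averages derived per-bin quantities; recomputing gain
  and phase from band-integrated spectra would weight bins by MAP power
  and can differ slightly when in-band spectra are far from flat.
* The normalised-gain convention (`gain × mean MAP / mean MCAv`) is the
  magnitude-consistent reading of "percent per percent" used in the
  cerebral-autoregulation literature; other groups normalise by setpoint
  values instead of recording means.
* The exact signed-rank null is enumerated per test; at the study's
  n ≈ 10 this is instantaneous, but the implementation switches to the
  corrected normal approximation beyond n = 20.
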