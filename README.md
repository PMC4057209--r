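# dcar — transfer function analysis of dynamic cerebral autoregulation

`dcar` is an R package for quantifying **dynamic cerebral autoregulation**
from paired recordings of mean arterial blood pressure (MAP, mmHg) and
transcranial Doppler middle cerebral artery blood flow velocity (MCAv,
cm/s), for physiologists and intensive-care researchers studying how the
brain buffers spontaneous pressure fluctuations — for example before and
after experimental endotoxaemia, or under hyperoxic and hypoxic
challenges.

## What it computes

Treating the cerebral circulation as a linear system with MAP as input
and MCAv as output, the package estimates Welch auto- and cross-spectra
(1200-point segments at 10 Hz, 60 s overlap, Hanning taper, per-segment
mean removal) and derives, in the very-low (0.02–0.07 Hz), low
(0.07–0.20 Hz) and high (0.20–0.30 Hz) frequency bands:

| quantity | definition | units |
|---|---|---|
| transfer gain | `Mod(S_xy) / S_xx` | cm s⁻¹ mmHg⁻¹ |
| normalised gain | `gain × mean(MAP)/mean(MCAv)` | %/% |
| phase difference | `Arg(S_xy)`, positive = MCAv leads | rad |
| squared coherence | `Mod(S_xy)² / (S_xx · S_yy)` | – |
| MAP_sp, MCAv_sp | band-integrated spectral power | mmHg², cm² s⁻² |

Band estimates with coherence < 0.4 are flagged invalid, and subjects
failing the criterion are excluded from autoregulation summaries (with a
logged reason) but retained elsewhere. A rising low-frequency phase or a
falling gain is interpreted as enhanced autoregulation
(`interpret_direction()`).

Around the spectral core the package provides:

* **cerebral oxygen vasoreactivity** — percent change in MCAv per kPa
  change in PaO2 (or per mM change in arterial oxygen content,
  `CaO2 = SaO2 × Hb + 0.01 × PaO2`), from trailing four-minute means,
  hyperoxia and hypoxia assessed separately;
* **paired nonparametric cohort statistics** — exact Wilcoxon signed-rank
  tests (full-enumeration null, exact with ties), Holm step-down
  adjustment within comparison families, median–IQR summaries;
* **a synthetic hemodynamic-signal generator** — Mayer-wave/respiratory
  MAP oscillations passed through configurable linear transfer models
  with known gain/phase ground truth, plus blood-gas panels and whole
  cohorts, so the entire pipeline is testable without clinical data.

## Worked example

Simulate a 10-subject study (two conditions × three oxygen
interventions, 20-minute recordings) in which the inflammatory condition
raises the true low-frequency phase from 0.58 to 0.82 rad, then run the
full analysis:

```r
library(dcar)

effect <- cohort_effect_config(n_subjects = 10, seed = 1)
cohort <- simulate_cohort(effect, realisation_seed = 2L)
result <- run_study(cohort)

subset(result$tfa_summary,
       band == "LF" & metric == "phase" & intervention == "normoxia")
#>   band condition intervention metric  n median    q1    q3
#> 1   LF       LPS     normoxia  phase 10  0.847 0.749 0.884
#> 2   LF  baseline     normoxia  phase 10  0.610 0.458 0.676

subset(result$comparisons,
       band == "LF" & metric == "phase" & family == "lps_vs_baseline")
#>   band metric          family                 comparison  n statistic   p_raw  p_holm
#> 1   LF  phase lps_vs_baseline  normoxia: LPS vs baseline 10        55 0.00195 0.00586
#> 2   LF  phase lps_vs_baseline hyperoxia: LPS vs baseline 10        55 0.00195 0.00586
#> 3   LF  phase lps_vs_baseline   hypoxia: LPS vs baseline 10        55 0.00195 0.00586
```

The cohort median low-frequency phase rises from 0.61 to 0.85 rad
(recovering the simulated 0.58 → 0.82 effect to within the sampling
variability of ten subjects), and the paired exact Wilcoxon test flags
the increase with Holm-adjusted p = 0.0059 — evidence of enhanced
phase-lead under the condition, while gain stays unchanged. The
vasoreactivity summary likewise recovers the configured slopes
(baseline medians −0.72 %/kPa hyperoxic, −1.07 %/kPa hypoxic):

```r
result$covr_summary[, 1:6]
#>   condition direction  n slope_pao2_median slope_pao2_q1 slope_pao2_q3
#> 1       LPS hyperoxia 10            -0.222        -0.298      0.000936
#> 2       LPS   hypoxia 10            -2.059        -2.160     -1.913398
#> 3  baseline hyperoxia 10            -0.719        -0.793     -0.501110
#> 4  baseline   hypoxia 10            -1.066        -1.167     -0.894669

render_tables(result, "results/tables")   # CSV tables, one block per band
```

A thin command-line interface over the same functions is installed as
`exec/dcar` (`dcar simulate`, `dcar tfa`, `dcar covr`, `dcar study`);
recordings are plain CSV files with header `time_s,map_mmHg,mcav_cm_s`.

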