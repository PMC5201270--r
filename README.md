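# repolsig

ECG repolarization biomarkers for detecting drug-induced late sodium
current block.

## The problem

Blocking the hERG potassium channel prolongs the heart-rate-corrected QT
interval (QTc) and raises torsade-de-pointes risk. Drugs that *also* block
the late sodium current (e.g. ranolazine, or dofetilide co-administered
with mexiletine or lidocaine) can prolong QTc by a similar amount with much
lower risk. The early repolarization interval — J point to T-wave peak,
heart-rate corrected (**J-Tpeakc**, exponential correction
`J-Tpeakc = J-Tpeak / RR^0.58`) — separates the two mechanisms: selective
hERG block prolongs it, adding late sodium block pulls it back toward zero
while QTc stays elevated.

`repolsig` implements, for clinical pharmacologists and ECG methodologists,
the complete analysis chain around that observation:

* a **calibrated synthetic crossover trial** (21 subjects, five periods:
  placebo, dofetilide, moxifloxacin, mexiletine+dofetilide,
  lidocaine+dofetilide) with one-compartment pharmacokinetics, per-subject
  sensitivities, and 10-s multi-lead ECG waveform synthesis with ground
  truth — population drug responses are calibrated so that, e.g.,
  dofetilide at Cmax gives ddQTc ≈ 45 ms and ddJ-Tpeakc ≈ 29 ms while the
  combinations give ddQTc ≈ 17–18 ms and ddJ-Tpeakc ≈ 1–4 ms;
* **median-beat delineation** (R detection, per-sample median beat, QRS
  onset/offset, T peak, tangent-method T end) and **T-wave morphology**
  (kurtosis flatness, mirror asymmetry, ERD/LRD level crossings, amplitude,
  ventricular gradient);
* **heart-rate correction** (Fridericia `QT/RR^(1/3)`; exponential
  `biomarker/RR^alpha` with data-driven exponent estimation and a sex
  test);
* **exposure-response**: placebo-corrected changes from baseline (ΔΔ) via a
  crossover mixed model, concentration-response with random
  intercept+slope, ECG signature curves at 25% Cmax increments, mitigation
  paired t-tests, Cohen's d;
* **classification** of multichannel vs selective hERG block: logistic
  ROC analysis with stratified-bootstrap CIs and DeLong comparisons, the
  fixed decision rule (ΔΔJ-Tpeakc > 9 ms → hERG; else ΔΔQTc ≤ 29 ms →
  multichannel; else inconclusive), and a small gain-ratio tree learner
  with 10-fold cross-validation.

## Worked example

```r
library(repolsig)
library(dplyr)

trial   <- simulate_trial(trial_design(seed = 42))          # fast biomarker path
changes <- changes_from_baseline(correct_biomarkers(trial))

delta_delta(changes) |>
  filter(timepoint_h == 13, biomarker %in% c("qtc_ms", "jtpeakc_ms"))
#>    biomarker                     arm estimate ci_low ci_high
#>  jtpeakc_ms              dofetilide     25.1   17.7    32.4
#>  jtpeakc_ms  (lidocaine+dofetilide)      3.5   -3.8    10.8
#>  jtpeakc_ms (mexiletine+dofetilide)     -2.1   -9.4     5.2
#>  jtpeakc_ms            moxifloxacin      5.4   -1.9    12.8
#>      qtc_ms              dofetilide     43.9   35.8    51.9
#>      qtc_ms  (lidocaine+dofetilide)     17.1    9.0    25.1
#>      qtc_ms (mexiletine+dofetilide)     15.0    7.0    23.1
#>      qtc_ms            moxifloxacin     11.4    3.4    19.5
```

Dofetilide alone prolongs both QTc (+44 ms) and J-Tpeakc (+25 ms); the
late-sodium combinations keep roughly +16 ms of QTc prolongation while
J-Tpeakc collapses to about 0 — the late-sodium signature.

```r
features <- classification_features(subject_delta_delta(changes))
roc_analysis(features,
             list(jtpeakc = "dd_jtpeakc_ms", qtc = "dd_qtc_ms",
                  flatness = "dd_flatness_c"),
             n_boot = 2000, seed = 42)
#>      model   auc auc_lo auc_hi sensitivity specificity
#>  1 jtpeakc 0.716  0.633  0.793       0.476       0.940
#>  2     qtc 0.642  0.558  0.725       0.417       0.857
#>  3 flatness 0.500  0.415  0.584      0.250       0.857

tree_classify(c(29.1, 1.1, 4.1), c(45.2, 17.3, 17.9))
#> [1] "hERG"         "multichannel" "multichannel"
```

J-Tpeakc discriminates multichannel from selective hERG block better than
QTc (AUC 0.72 vs 0.64 here), flatness adds nothing, and the fixed
J-Tpeakc/QTc rule classifies the population mean changes of the three
active regimens correctly. `run_pipeline(pipeline_config(seed = 42))` runs
the same chain end to end, persisting every stage table and a manifest;
`autoplot()` methods exist for ROC tables, ROC curves and signature
predictions, and `tidy()`/`glance()` for the fitted objects.

The methods vignette (`vignettes/repolsig-methods.Rmd`) documents the beat
model, the calibration targets, every default with its unit, and the known
limitations of the synthetic data.

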