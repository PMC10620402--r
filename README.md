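# sanclock

Beat-interval variability (BIV/HRV) analysis of RR tachograms, with FIR
band-stop "signature" filters that emulate pharmacological states —
propofol/dexmedetomidine anesthesia and full autonomic blockade
(atropine + propranolol, "ABK") — from basal ECG-derived recordings.

## The problem

The sinoatrial node's beating rhythm is set jointly by the autonomic
nervous system (ANS) and the node's intrinsic "coupled-clock"
machinery. Separating the two normally requires pharmacological
denervation, which is invasive and, in young patients, only feasible
under anesthesia. Because the two systems occupy different regions of
the RR power spectrum — the ANS dominates the LF/HF bands and
short-term variability, the intrinsic system the VLF band and
long-range structure — a band-stop filter on the tachogram can remove
one system's spectral contribution and make a basal recording *look
like* a blockade (or anesthesia) recording. `sanclock` implements that
idea end to end for clinicians and physiologists studying sinoatrial
function and its age dependence:

* **cleaning** — the three standard non-physiological-beat filters
  (range 0.28–2.4 s; 21-beat moving-average at 20%; quotient at 20%);
* **metrics** — AVNN, SDNN, RMSSD, pNN50 and Poincaré SD1/SD2;
* **spectra** — Welch (4 Hz resampled grid) and Lomb–Scargle PSDs with
  absolute and normalized VLF/LF/HF band powers;
* **complexity** — multiscale sample entropy (Richman–Moorman, Costa
  coarse-graining; `m = 2`, `r = 0.2·SD`, scales 1–20);
* **signature filters** — windowed-sinc FIR band-stop filters (Blackman
  taper, order 100 mono / 150 dual), applied zero-phase on a 4 Hz
  tachogram grid. Four published presets ship with the package:

  | preset | stop bands (Hz) | applied to | emulates |
  |---|---|---|---|
  | `young-anesthesia` | 0.013–0.03 + 0.046–0.158 | basal | anesthesia |
  | `adult-anesthesia` | 0.03–0.2 | basal | anesthesia |
  | `young-abk` | 0.05–0.58 | anesthesia | blockade |
  | `adult-abk` | 0.015–0.14 + 0.16–0.58 | basal | blockade |

* **validation** — per-scale t-tests of MSE curves averaged into a mean
  p-value (high = emulation succeeded), BH-FDR adjustment, and the
  age-linear blockade laws `RR = 515.75 + 4.01·age` (ms) and
  `IHR = 113 − 0.54·age` (bpm);
* **synthetic cohorts** — a calibrated generator producing RR series
  with the reported state means (young 680/987/572 ms, adult
  874/1115/732 ms for basal/anesthesia/blockade), the anesthesia HF
  inflation, the ~100× blockade power collapse, and the age law, so the
  whole pipeline is testable without clinical recordings.

## Worked example

```r
library(sanclock)

s <- generate_rr_series("BSL", "young", duration = 600, seed = 42)
clean <- preprocess_pipeline(s)
print(clean$report)
#> Cleaning report: 887 beats in, 885 kept
#>   removed: range 0, moving-average 1, quotient 1

time_domain_metrics(clean$series)
#> BIV report (885 beats): AVNN 676.3 ms, SDNN 50.01 ms, RMSSD 37.22 ms,
#>   pNN50 17.1%, SD1 26.32 ms, SD2 65.64 ms

band_powers(compute_psd(clean$series))
#> PSD (welch estimator), 513 frequencies up to 2 Hz
#>   total power 2565 ms^2
#>   VLF: 848.3 ms^2 (35.9%)
#>   LF: 548.7 ms^2 (23.2%)
#>   HF: 963 ms^2 (40.8%)

# emulate the anesthesia state from the basal recording
emu <- apply_signature(clean$series, "young-anesthesia")
multiscale_entropy(emu)$sampen[1]
#> [1] 1.67   # scale-1 entropy of the emulated series
```

The cleaned basal recording has a mean beat interval of ~676 ms (the
calibrated young basal mean is 680 ms) and a broadband spectrum; after
the anesthesia signature filter its scale-1 sample entropy (1.67) sits
next to that of a genuine synthetic anesthesia recording (1.78),
which is what the filter is for.

`run_full_study("out/", seed = 1)` runs the whole study — simulation,
cleaning, metric/band/MSE tables, all four emulations with similarity
reports, and the age regressions — and writes a manifest tying every
output to the seed and configuration hash.

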