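# Packaged default configuration.
#
# State means (ms), inter-subject spreads and cohort sizes are the reported
# clinical values. The within-subject spectral amplitude constants (ms RMS
# per component) are calibration choices, tuned once and then frozen, so
# that the synthetic states reproduce the reported structure: anesthesia
# inflates normalized HF and suppresses normalized VLF in the young,
# autonomic blockade (ABK) collapses total tachogram power by about two
# orders of magnitude with VLF dominance, basal multiscale entropy stays
# near-flat, and each non-basal state's spectrum is the basal spectrum
# shaped by the squared two-pass response of its signature filter, so the
# filters' emulation fidelity is measurable on synthetic cohorts.

grid_fs: 4.0            # Hz, uniform tachogram processing grid

states:
  young:
    BSL:
      mean_bi: 680.0
      subject_sd: 140.0
      band_amp: {VLF: 4.0, LF: 20.0, HF: 22.0}
      one_over_f_amp: 42.0
      resp_peak: {freq: 0.27, width: 0.03, amp: 26.0}
      hf_plateau: [0.2, 0.4]
      total_sd: 50.0
      shape: []
    Anesthesia:
      mean_bi: 987.0
      subject_sd: 172.0
      band_amp: {VLF: 4.0, LF: 20.0, HF: 22.0}
      one_over_f_amp: 42.0
      resp_peak: {freq: 0.27, width: 0.03, amp: 26.0}
      hf_plateau: [0.2, 0.4]
      total_sd: 50.0
      shape: [young-anesthesia]
    ABK:
      mean_bi: 572.0
      subject_sd: 72.0
      band_amp: {VLF: 4.0, LF: 20.0, HF: 22.0}
      one_over_f_amp: 42.0
      resp_peak: {freq: 0.27, width: 0.03, amp: 26.0}
      hf_plateau: [0.2, 0.4]
      total_sd: 5.0
      shape: [young-anesthesia, young-abk]
  adult:
    BSL:
      mean_bi: 874.0
      subject_sd: 120.0
      band_amp: {VLF: 14.0, LF: 22.0, HF: 12.0}
      one_over_f_amp: 12.0
      resp_peak: {freq: 0.25, width: 0.03, amp: 14.0}
      slow_peak: {freq: 0.006, width: 0.002, amp: 32.0}
      lf_plateau: [0.04, 0.13]
      hf_plateau: [0.17, 0.4]
      total_sd: 40.0
      shape: []
    Anesthesia:
      mean_bi: 1115.0
      subject_sd: 187.0
      band_amp: {VLF: 14.0, LF: 22.0, HF: 12.0}
      one_over_f_amp: 12.0
      resp_peak: {freq: 0.25, width: 0.03, amp: 14.0}
      slow_peak: {freq: 0.006, width: 0.002, amp: 32.0}
      lf_plateau: [0.04, 0.13]
      hf_plateau: [0.17, 0.4]
      total_sd: 40.0
      shape: [adult-anesthesia]
    ABK:
      mean_bi: 732.0
      subject_sd: 130.0
      band_amp: {VLF: 14.0, LF: 22.0, HF: 12.0}
      one_over_f_amp: 12.0
      resp_peak: {freq: 0.25, width: 0.03, amp: 14.0}
      slow_peak: {freq: 0.006, width: 0.002, amp: 32.0}
      lf_plateau: [0.04, 0.13]
      hf_plateau: [0.17, 0.4]
      total_sd: 4.0
      shape: [adult-abk]

age_law:
  intercept: 515.75     # ms
  slope: 4.01           # ms / year
  noise_sd: 40.0        # ms, inter-subject scatter about the law

ihr_law:                # heart-rate-space counterpart, bpm
  intercept: 113.0
  slope: -0.54

bands:
  vlf: [0.0033, 0.04]
  lf: [0.04, 0.15]
  hf: [0.15, 0.4]

bands_wide_hf:
  vlf: [0.0033, 0.04]
  lf: [0.04, 0.15]
  hf: [0.15, 0.6]

mse:
  S: 20
  m: 2
  r_fraction: 0.2

cleaning:
  rr_min: 0.28          # s
  rr_max: 2.4           # s
  ma_window: 21
  ma_threshold: 0.2
  quotient_threshold: 0.2

cohort:
  n_young: 16
  n_adult: 23
  duration: 600.0       # s per recording
  ages_young: [5, 19]
  ages_adult: [41, 78]

# Held-out emulation-fidelity experiment: group size per arm, recording
# length (the 10-15 min segments used for the pharmacological states),
# and the number of replicate cohorts whose median similarity is scored.
emulation:
  n_per_group: 16
  duration: 900.0
  replicates: 7

presets:
  young-anesthesia:
    stop_bands: [[0.013, 0.03], [0.046, 0.158]]
    source_state: BSL
    target_state: Anesthesia
  adult-anesthesia:
    stop_bands: [[0.03, 0.2]]
    source_state: BSL
    target_state: Anesthesia
  young-abk:
    stop_bands: [[0.05, 0.58]]
    source_state: Anesthesia
    target_state: ABK
  adult-abk:
    stop_bands: [[0.015, 0.14], [0.16, 0.58]]
    source_state: BSL
    target_state: ABK
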