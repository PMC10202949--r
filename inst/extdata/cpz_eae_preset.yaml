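# Calibrated four-group study preset: control, untreated disease
# (inflammatory demyelination), and two treated arms. All tuned constants of
# the cohort generator live here; the code only applies them.
#
# The latent inflammation burden b ~ N(group mean, sigma) drives every
# readout. Group means on the burden scale are derived from the designed
# lactate/pyruvate fold changes via the log-linear kPL link
# (kPL = kpl_base * exp(slope_log_kpl * b)), so the expected lac/pyr group
# contrasts equal the designed folds exactly. Markers use per-group linear
# links value = group_mean + slope * (b - mu_g) + N(0, cv * group_mean),
# truncated at zero; the shared slope (fitted across the four designed group
# means) carries the within-cohort correlation structure.

groups: [control, cpz_eae, cpz_eae_dmf, cpz_eae_fty720]
n_animals: [14, 12, 11, 14]

latent:
  sigma: 0.3
  # within-group burden-driven coefficient of variation of each marker and
  # of the T1 volume: the per-group link slope is
  # direction * (burden_cv / sigma) * group_mean, so within-group spread
  # scales with the group mean and zero-truncation stays negligible even
  # for near-zero control means
  burden_cv: 0.25

kinetics:
  kpl_base: 0.02          # 1/s, control median conversion rate
  slope_log_kpl: 1.0
  lacpyr_fold_disease_vs_control: 2.1
  lacpyr_fold_decrease_dmf: 1.31
  lacpyr_fold_decrease_fty720: 1.35
  urea_amp_base: 1.0
  urea_log_slope: 0.0     # urea delivery independent of disease burden

eae:
  # designed mean clinical scores; groups at 0 use a floored latent so the
  # ordinal score never leaves category 0
  target_score: [0.0, 2.6, 1.1, 0.0]
  latent_slope: 1.0
  latent_sd: 0.8
  floor_latent: -3.0
  euthanasia_score: 4

markers:
  # per-group designed means (control, disease, disease+DMF, disease+FTY720)
  # cv: noise standard deviation as a fraction of the group mean
  pdh_activity:        {means: [8.0, 0.988, 3.654, 3.160], cv: 0.15, direction: decrease, unit: "nmol/min/mg"}
  ldh_activity:        {means: [120, 120, 120, 120],       cv: 0.12, direction: none,     unit: "nmol/min/mg"}
  iba1_area:           {means: [2.0, 14.0, 7.37, 8.75],    cv: 0.18, direction: increase, unit: "% area"}
  cd68_area:           {means: [0.4, 10.0, 4.0, 10.0],     cv: 0.20, direction: increase, unit: "% area"}
  cd3_count:           {means: [0.5, 227.5, 68.9, 11.5],   cv: 0.25, direction: increase, unit: "cells/mm^2"}
  pdk1_area:           {means: [0.1, 9.5, 3.8, 3.28],      cv: 0.20, direction: increase, unit: "% area"}
  gfap_area:           {means: [4.0, 14.0, 14.0, 14.0],    cv: 0.15, direction: increase, unit: "% area"}
  fibrinogen_area:     {means: [0.5, 2.5, 2.2, 0.5],       cv: 0.20, direction: increase, unit: "% area"}
  myelin_area:         {means: [60, 35, 45, 45],           cv: 0.10, direction: decrease, unit: "% area"}

t1_enhancement:
  # designed enhancing volumes (mm^3); disease 5.2-fold and DMF 3.0-fold
  # over control, treated-FTY720 at control level
  means: [0.3, 1.56, 0.9, 0.3]
  cv: 0.20
  lesion_fraction: 0.5
  image_noise_sigma: 0.02

csi:
  # k-space noise per complex component; gives a time-summed-spectrum SNR of
  # roughly 300 on pyruvate and 20 on lactate at the control conversion rate,
  # in line with the clean summed spectra hyperpolarized studies report
  noise_sigma: 0.0005
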