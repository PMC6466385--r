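# Canine study configuration: published morphometry and physiology,
# with the synthetic-study design standing in for the measured series.
seed: 1

histology:
  vessel_area_ratio_pct: 12.3   # smooth-muscle-actin lumen area, %
  hematocrit: 0.45
  cell_area_ratio_pct: 61.7     # HE nucleus count summary, %
  fat_fraction_pct: 11.7
  collagen_fraction_pct: 3.9

subject:
  body_weight_kg: 9.3
  dose_mg_per_kg: 2.5
  blood_fraction: 0.077         # blood mass fraction of body weight
  plasma_fraction: 0.55         # 1 - hematocrit
  reference_tissue_volume_ml: 1221  # glucose distribution volume

design:
  plasma_times_min: [0, 5, 10, 15, 20, 30, 40, 50, 60, 70, 75, 85]
  fluorescence_times_min: [0, 10, 40]
  noise_model: proportional
  noise_cv: 0.05
  true_k: {k10: 0.045, k12: 0.145, k21: 0.27, k23: 0.43, k32: 0.36}
  true_Rmyo: 189

fit:
  n_starts: 20
  k_max: 10
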