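# SYNTHETIC one-way sensitivity scenarios mirroring the usual perturbation
# classes: fee changes, complication-rate changes, CMR accuracy changes,
# FFR-threshold (link) swap, and outpatient/inpatient setting swap.
- label: CMR sensitivity set to 0.80
  perturbation: absolute_set
  parameter: sn_cmr
  magnitude: 0.80
- label: FN complication rate doubled
  perturbation: relative_scale
  parameter: r_f
  magnitude: 2.0
- label: CMR fee +10%
  perturbation: relative_scale
  parameter: f_cmr
  magnitude: 1.1
- label: FFR-0.80 calibration link
  perturbation: swap_link
  link_form: linear_clipped
  link_parameters: [0.05, 1.0]
  ffr_threshold_label: "0.80"
- label: inpatient angiography
  perturbation: swap_setting
  setting: inpatient
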