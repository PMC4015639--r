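country_label: Synthetica
provenance_note: >-
  SYNTHETIC example fee schedule for demonstration and testing; these are
  not the published fees of any health-care system.
currency: XXX
costs:
  f_cmr: 1000
  f_cxa_outpatient: 2000
  f_cxa_inpatient: 3500
  f_ffr: 600
  c_complication: 10000
  discount_rate: 0.03
  horizon_years: 10
  cxa_setting: outpatient
performance:
  sn_cmr: 0.88
  sp_cmr: 0.90
  ndx: 0.05
  r_cxa: 0.0005
  r_f: 0.15
link_form: identity
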