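# Machine templates shipped with vmatcx.
#
# Leaf geometry (widths, overtravel) follows the two modeled MLC designs.
# The kinematic limits are ASSUMPTIONS: typical configuration values for
# these system classes, editable here; they are not vendor specifications.
machines:
- name: millennium120
  leaf_widths_cm: [1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
                   0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
                   0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
                   0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
                   0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
                   1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0]
  overtravel_cm: 15.0
  min_gap_cm: 0.0
- name: elektaMLCi
  leaf_widths_cm: [1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
                   1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
                   1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
                   1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0]
  overtravel_cm: 12.5
  min_gap_cm: 0.0
constraints:
- max_gantry_speed_deg_s: 4.8
  max_dose_rate_mu_min: 600.0
  dose_rate_mode: continuous
  dose_rate_bins_mu_min: ~
  max_leaf_speed_cm_s: 2.5
- max_gantry_speed_deg_s: 6.0
  max_dose_rate_mu_min: 600.0
  dose_rate_mode: binned
  dose_rate_bins_mu_min: [600.0, 300.0, 150.0, 75.0, 37.5]
  max_leaf_speed_cm_s: 2.0
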