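# Bundled polymerase presets.  Coefficients were calibrated analytically
# against the generative model (see the methods vignette): free terms were
# solved so that assay-level mean gains, Ca2+ fold changes and the Klenow
# lag-one excess reproduce the published headline values under the default
# noise floor of 1e-3 substitutions per template base.
dpo4_paper:
  name: dpo4_paper
  heterogeneity_shape: 2
  lag1_boost: 0
  truncation_prob: 3.0e-3
  indel_prob: 2.0e-4
  r_max: 0.5
  rate_params:
    A:
      r0: 5.0e-05
      mn: {a: 0.0003, gamma: 1}
      mg: {a: 5.0e-05, gamma: 1}
    C:
      r0: 5.0e-05
      mn: {a: 0.0003, gamma: 1}
      mg: {a: 5.0e-05, gamma: 1}
    G:
      r0: 5.0e-05
      mn: {a: 0.0003, gamma: 1}
      mg: {a: 5.0e-05, gamma: 1}
    T:
      r0: 0
      mn: {a: 0.104544749844, gamma: 2.2}
      mg: {a: 0.00025, gamma: 1}
  transition_rows:
    A: {A: 0.5, C: 0.25, G: 0.25}
    C: {A: 0.5, C: 0.25, T: 0.25}
    G: {A: 0.5, G: 0.25, T: 0.25}
    T: {C: 0.1, G: 0.8, T: 0.1}
  ca_modifier:
    mn_bg: {breaks_uM: [0.1, 1000], mult: [1, 5.16368372776]}
    mg_bg: {breaks_uM: [100, 1000], mult: [1, 0.00991192517984]}
klenow_paper:
  name: klenow_paper
  heterogeneity_shape: 4
  lag1_boost: 0.0676752921848
  truncation_prob: 3.0e-3
  indel_prob: 2.0e-4
  r_max: 0.5
  rate_params:
    A:
      r0: 0.0012
      mn: {a: 0.00831967734324, gamma: 1}
      mg: {a: -9.33779595977e-05, gamma: 1}
    C:
      r0: 0.001
      mn: {a: 0.00369763437477, gamma: 1}
      mg: {a: -9.33779595977e-05, gamma: 1}
    G:
      r0: 0.002
      mn: {a: 0.00184881718739, gamma: 1}
      mg: {a: -9.33779595977e-05, gamma: 1}
    T:
      r0: 0.0012
      mn: {a: 0.00831967734324, gamma: 1}
      mg: {a: -9.33779595977e-05, gamma: 1}
  transition_rows:
    A: {A: 0.7, C: 0.15, G: 0.15}
    C: {A: 0.7, C: 0.15, T: 0.15}
    G: {A: 0.7, G: 0.15, T: 0.15}
    T: {C: 0.12, G: 0.76, T: 0.12}
phusion_control:
  name: phusion_control
  heterogeneity_shape: "Inf"
  lag1_boost: 0
  truncation_prob: 3.0e-3
  indel_prob: 2.0e-4
  r_max: 0.5
  rate_params:
    A:
      r0: 0
    C:
      r0: 0
    G:
      r0: 0
    T:
      r0: 0
  transition_rows:
    A: {A: 0.333333333333, C: 0.333333333333, G: 0.333333333333}
    C: {A: 0.333333333333, C: 0.333333333333, T: 0.333333333333}
    G: {A: 0.333333333333, G: 0.333333333333, T: 0.333333333333}
    T: {C: 0.333333333333, G: 0.333333333333, T: 0.333333333333}
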