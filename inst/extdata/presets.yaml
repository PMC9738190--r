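# Drug-condition preset registry.
#
# Kinds:
#   set                   -- absolute parameter targets (idempotent)
#   scale                 -- multiplicative edits (double application refused)
#   recalibrate_baseline  -- root-solve the clearance Vmax to a target
#                            resting extracellular histamine
#   identity              -- no-op
#
# The scale factors and the post-thioperamide female baseline target are
# calibration values (chosen so simulated amplitude/clearance changes fall in
# the experimentally observed ranges), not measured quantities.
format_version: 1
presets:
  control:
    kind: identity
  immepip:
    kind: set
    set:
      alpha: 1.9
  thioperamide_male:
    kind: set
    set:
      alpha: 0.0
  thioperamide_female:
    kind: recalibrate_baseline
    target_eHA_uM: 14.6
  reserpine:
    kind: scale
    scale:
      V_MAT: 0.5
  tetrabenazine:
    kind: scale
    scale:
      V_MAT: 0.5
  fmh:
    kind: scale
    scale:
      V_HTDC: 0.6
  tacrine:
    kind: scale
    scale:
      V_HNMT_g: 0.82
      V_HNMT_c: 0.82
  zolantidine:
    kind: identity
  dph:
    kind: set
    set:
      s_strength: 0.0
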