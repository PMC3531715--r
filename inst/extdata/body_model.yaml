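# Five-segment planar gymnast model (one upper and one lower limb digitized,
# bilateral limb segments doubled). Mass fractions follow adjusted
# cadaver-based anthropometric tables: head mass is folded into the trunk,
# hand mass into the forearm, foot mass into the shank, so the five fractions
# sum to exactly 1. CG and radius-of-gyration fractions are measured from the
# `from` marker (the bar-proximal end of each segment). Lengths in metres.
body_mass: 65
gravity: 9.81
segments:
  forearm:
    from: wrist
    to: elbow
    mass_fraction: 0.0446
    cg_fraction: 0.57
    gyration_fraction: 0.27
    length: 0.28
  arm:
    from: elbow
    to: shoulder
    mass_fraction: 0.0542
    cg_fraction: 0.42
    gyration_fraction: 0.28
    length: 0.30
  trunk:
    from: shoulder
    to: hip
    mass_fraction: 0.5040
    cg_fraction: 0.45
    gyration_fraction: 0.37
    length: 0.55
  thigh:
    from: hip
    to: knee
    mass_fraction: 0.2832
    cg_fraction: 0.41
    gyration_fraction: 0.33
    length: 0.45
  shank:
    from: knee
    to: ankle
    mass_fraction: 0.1140
    cg_fraction: 0.44
    gyration_fraction: 0.30
    length: 0.45
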