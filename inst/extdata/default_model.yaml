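# Default planar elbow + exosuit model configuration (SI units).
# Segment, load and anchorage values define the default conditions of the
# package's elbow-flexion task sweep; the muscle set is the packaged
# six-muscle fixture.
segment:
  forearm_mass: 1.53          # kg
  com_distance: 0.18          # m, elbow -> forearm COM
  inertia_about_elbow: 0.02   # kg m^2, sagittal-plane component
  upper_arm_orientation: 0.0  # rad, shoulder locked, upper arm vertical
load:
  external_mass: 0.0          # kg (task sweep uses 0, 2, 5)
  load_distance: 0.35         # m, elbow -> load
exosuit:
  arm_anchor: [0.04, 0.14]      # m, upper-arm frame (x anterior, y proximal)
  forearm_anchor: [0.02, 0.15]  # m, forearm frame (offset, along-axis)
gravity: 9.81                 # m/s^2, downward
inertia_frame: elbow          # 'elbow': table value used as-is; 'com': add m*lc^2
muscles: arm26                # packaged fixture; or an inline list of 6 muscles
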