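# Six-muscle elbow parameter set (synthetic reconstruction).
#
# Provenance
# ----------
# * max_isometric_force [N], optimal_fiber_length [m], tendon_slack_length [m],
#   pennation_at_optimal [rad] and the activation/deactivation time constants
#   [s] are transcribed from the publicly documented "arm26" OpenSim example
#   model (Thelen-type muscles; values widely reproduced in the open
#   literature on upper-extremity modelling).
# * moment_arm_coeffs are polynomial coefficients (ascending powers of the
#   elbow flexion angle theta [rad], valid on [-0.1, 1.8] rad) giving the
#   SIGNED elbow moment arm [m] (+ flexion).  The curves are a synthetic
#   polynomial reconstruction matched to published elbow moment-arm
#   measurements (biceps peaking near 4.5 cm around 80-100 deg of flexion,
#   brachialis near 2.5-3 cm, triceps extension moment arm near 2-2.5 cm,
#   weakly angle-dependent).  They are labelled synthetic because they are
#   fitted stand-ins for wrapped muscle paths, not measured ones.
# * mtu_length_coeffs are the EXACT polynomial antiderivatives of
#   -moment_arm(theta), so d(MTU length)/d theta = -sign * |moment arm| holds
#   identically.  The integration constants calibrate the fiber operating
#   range: flexor fibers pass through optimal length at theta = 0.8 rad,
#   extensor fibers at theta = 1.2 rad (rigid tendon, constant-thickness
#   pennation model).
# * origin_xy [m, upper-arm frame, elbow at origin, x anterior, y proximal]
#   and insertion_s / insertion_offset [m, along / perpendicular to the
#   forearm axis] are EFFECTIVE straight-line attachment points used only to
#   orient muscle force vectors in the joint-reaction force balance; they are
#   a synthetic stand-in for the wrapped muscle paths of the source model.
# * fast_twitch_fraction (dimensionless) feeds the muscle energetics model;
#   values are standard literature estimates for elbow flexors/extensors.
# * sign: +1 elbow flexor, -1 elbow extensor.
muscles:
  - name: biceps_long
    sign: 1
    max_isometric_force: 624.3
    optimal_fiber_length: 0.1157
    tendon_slack_length: 0.2723
    max_contraction_velocity: 10.0
    pennation_at_optimal: 0.0
    act_time_constant: 0.010
    deact_time_constant: 0.040
    fast_twitch_fraction: 0.50
    moment_arm_coeffs: [0.020, 0.035, -0.012]
    mtu_length_coeffs: [0.413152, -0.020, -0.0175, 0.004]
    origin_xy: [0.015, 0.30]
    insertion_s: 0.045
    insertion_offset: 0.015
  - name: biceps_short
    sign: 1
    max_isometric_force: 435.56
    optimal_fiber_length: 0.1321
    tendon_slack_length: 0.1923
    max_contraction_velocity: 10.0
    pennation_at_optimal: 0.0
    act_time_constant: 0.010
    deact_time_constant: 0.040
    fast_twitch_fraction: 0.50
    moment_arm_coeffs: [0.022, 0.030, -0.010]
    mtu_length_coeffs: [0.3498933, -0.022, -0.015, 0.0033333333]
    origin_xy: [0.020, 0.28]
    insertion_s: 0.050
    insertion_offset: 0.015
  - name: brachialis
    sign: 1
    max_isometric_force: 987.26
    optimal_fiber_length: 0.0858
    tendon_slack_length: 0.0535
    max_contraction_velocity: 10.0
    pennation_at_optimal: 0.0
    act_time_constant: 0.010
    deact_time_constant: 0.040
    fast_twitch_fraction: 0.50
    moment_arm_coeffs: [0.018, 0.012, -0.004]
    mtu_length_coeffs: [0.1568573, -0.018, -0.006, 0.0013333333]
    origin_xy: [0.012, 0.10]
    insertion_s: 0.030
    insertion_offset: 0.010
  - name: triceps_long
    sign: -1
    max_isometric_force: 798.52
    optimal_fiber_length: 0.1340
    tendon_slack_length: 0.1430
    max_contraction_velocity: 10.0
    pennation_at_optimal: 0.209
    act_time_constant: 0.010
    deact_time_constant: 0.040
    fast_twitch_fraction: 0.55
    moment_arm_coeffs: [-0.025, 0.003]
    mtu_length_coeffs: [0.2462440, 0.025, -0.0015]
    origin_xy: [-0.020, 0.25]
    insertion_s: 0.025
    insertion_offset: -0.015
  - name: triceps_lateral
    sign: -1
    max_isometric_force: 624.3
    optimal_fiber_length: 0.1138
    tendon_slack_length: 0.0980
    max_contraction_velocity: 10.0
    pennation_at_optimal: 0.157
    act_time_constant: 0.010
    deact_time_constant: 0.040
    fast_twitch_fraction: 0.55
    moment_arm_coeffs: [-0.024, 0.003]
    mtu_length_coeffs: [0.1837605, 0.024, -0.0015]
    origin_xy: [-0.020, 0.20]
    insertion_s: 0.025
    insertion_offset: -0.015
  - name: triceps_medial
    sign: -1
    max_isometric_force: 624.3
    optimal_fiber_length: 0.1138
    tendon_slack_length: 0.0908
    max_contraction_velocity: 10.0
    pennation_at_optimal: 0.157
    act_time_constant: 0.010
    deact_time_constant: 0.040
    fast_twitch_fraction: 0.55
    moment_arm_coeffs: [-0.023, 0.0025]
    mtu_length_coeffs: [0.1774005, 0.023, -0.00125]
    origin_xy: [-0.018, 0.16]
    insertion_s: 0.025
    insertion_offset: -0.015
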