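# Reference teaching case: serial LAD stenoses with a collateralized
# chronic total occlusion of the RCA, right-dominant system.
# Voltages are mmHg-equivalent, resistances in ohm, currents in flow units.
#
# inflow_resistance and the collateral resistance are not anatomically
# prescribed; they were identified by grid-search calibration against the
# frozen baseline (sim1) probe ratios and bed flows and cross-validated on
# sim2-sim4 (see calibrate_unprinted_parameters()).  The near-normal left
# main alone is conventionally quoted at ~10 mohm (kept in metadata); that
# value does not reproduce the frozen flows.
name: reference_case
arterial_pressure: 100.0
venous_pressure: 5.0
inflow_resistance: 0.099
root_node: ostium
dominance: right
segments:
- id: LAD_prox
  proximal_node: ostium
  distal_node: LAD_mid
  resistance: 1.0e-9
- id: LAD_dist
  proximal_node: LAD_mid
  distal_node: LAD_distal
  resistance: 1.0e-9
- id: LCx_prox
  proximal_node: ostium
  distal_node: LCx_distal
  resistance: 1.0e-9
# the RCA has its own aortic ostium: it anchors at the arterial node,
# upstream of the left-main inflow resistance
- id: RCA_prox
  proximal_node: arterial
  distal_node: RCA_distal
  resistance: 1.0e-9
lesions:
- id: LAD1
  segment_id: LAD_prox
  resistance: 3.0
  description: 60% proximal LAD stenosis
- id: LAD2
  segment_id: LAD_dist
  resistance: 15.0
  description: 90% distal LAD stenosis
- id: LCx
  segment_id: LCx_prox
  resistance: 0.75
  description: 60% proximal LCx stenosis
- id: RCA
  segment_id: RCA_prox
  resistance: 10000.0
  description: chronic total occlusion of the proximal RCA
beds:
- id: LADmyo
  feeding_node: LAD_distal
  resistance: 10.0
  leaman_weight: 56.0
  drains_to: venous
- id: LCxmyo
  feeding_node: LCx_distal
  resistance: 20.0
  leaman_weight: 28.0
  drains_to: venous
- id: RCAmyo
  feeding_node: RCA_distal
  resistance: 30.0
  leaman_weight: 16.0
  drains_to: venous
collaterals:
- id: collateral
  donor_node: LAD_mid
  recipient_node: RCA_distal
  resistance: 5.0
probes:
- id: LAD_mid
  node: LAD_mid
- id: LAD_distal
  node: LAD_distal
- id: LCx_distal
  node: LCx_distal
- id: RCA_distal
  node: RCA_distal
scenarios:
- name: sim1
  overrides:
    LAD1: 3.0
    LAD2: 15.0
- name: sim2
  overrides:
    LAD1: 3.0
    LAD2: 0.1
- name: sim3
  overrides:
    LAD1: 0.1
    LAD2: 0.1
- name: sim4
  overrides:
    LAD1: 0.1
    LAD2: 15.0
metadata:
  documented_lms_resistance: 0.01
  nominal_inflow_resistance: 0.1
  calibration: grid search on sim1 targets, cross-validated on sim2-sim4
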