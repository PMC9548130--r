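# Protocol registry. Groups are class labels, aliases (CI = AVA/AVD/AVE;
# backward_motor = VA/DA/VD/DD/AS) or explicit neuron names, resolved
# against the connectome at run time; currents are nA injected into each
# member of the group for the whole run.
#
# The awb/awc/asi/ase/ash entries encode the simulated aversion protocols
# on a full C. elegans connectome (supplied by the user in the documented
# CSV/JSON dialects). The toy_* entries are the analogous protocols for
# the shipped oscillator toy fixture.

awb_only:
  stimulus:
    - {group: AWB, current_nA: 5.0}
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

awb_ci:
  stimulus:
    - {group: AWB, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

awc_ci:
  stimulus:
    - {group: AWC, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

asi_ci:
  stimulus:
    - {group: ASI, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

ase_ci:
  stimulus:
    - {group: ASE, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

ash_ci:
  stimulus:
    - {group: ASH, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

awb_ci_minus_AUA:
  stimulus:
    - {group: AWB, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  ablations: [AUA]
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

awb_ci_minus_RMG:
  stimulus:
    - {group: AWB, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  ablations: [RMG]
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

awb_ci_minus_AIB:
  stimulus:
    - {group: AWB, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  ablations: [AIB]
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

awb_ci_minus_AVB:
  stimulus:
    - {group: AWB, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  ablations: [AVB]
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

awb_ci_minus_SMB:
  stimulus:
    - {group: AWB, current_nA: 5.0}
    - {group: CI, current_nA: 0.9}
  ablations: [SMB]
  duration: 12
  readout_classes: [VA, DA, VD, DD, AS]

toy_sensor_only:
  stimulus:
    - {group: SN, current_nA: 0.05}
  duration: 12
  readout_classes: [MA, MB, MD]

toy_coactivation:
  stimulus:
    - {group: SN, current_nA: 0.05}
    - {group: CM, current_nA: 0.02}
  duration: 12
  readout_classes: [MA, MB, MD]

toy_coactivation_minus_IN:
  stimulus:
    - {group: SN, current_nA: 0.05}
    - {group: CM, current_nA: 0.02}
  ablations: [IN]
  duration: 12
  readout_classes: [MA, MB, MD]

toy_coactivation_minus_BY:
  stimulus:
    - {group: SN, current_nA: 0.05}
    - {group: CM, current_nA: 0.02}
  ablations: [BY]
  duration: 12
  readout_classes: [MA, MB, MD]
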