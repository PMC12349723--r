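# Synthetic receptor manifest for a multi-conformation counter-selective
# screen of an ABC transporter. Fourteen search boxes over five pump
# conformations: three drug-binding-domain (DBD) boxes and eleven
# nucleotide-binding-domain (NBD) boxes (each NBD sampled individually,
# plus one combined NBD box on the transition conformation). The box
# geometry below is SYNTHETIC (plausible magnitudes only, not taken from
# any structure); replace center/size with real grid parameters before
# docking real receptors. Conformations without a DBD box carry no
# pair_group and contribute no counter-selection ratio.
targets:
  - target_id: 4KSB_DBD
    conformation: 4KSB_open_inward
    domain_class: DBD
    pair_group: 4KSB
    box_center: [0.0, 0.0, 10.0]
    box_size: [40.0, 40.0, 44.0]
  - target_id: Transition_DBD
    conformation: transition
    domain_class: DBD
    pair_group: Transition
    box_center: [0.0, 2.0, 12.0]
    box_size: [38.0, 38.0, 42.0]
  - target_id: 3B5X_DBD
    conformation: 3B5X_closed_inward
    domain_class: DBD
    pair_group: 3B5X
    box_center: [1.0, -2.0, 14.0]
    box_size: [36.0, 36.0, 40.0]
  - target_id: 4KSB_NBD_1
    conformation: 4KSB_open_inward
    domain_class: NBD
    pair_group: 4KSB
    box_center: [-18.0, -10.0, -38.0]
    box_size: [30.0, 30.0, 30.0]
  - target_id: 4KSB_NBD_2
    conformation: 4KSB_open_inward
    domain_class: NBD
    pair_group: 4KSB
    box_center: [18.0, 10.0, -38.0]
    box_size: [30.0, 30.0, 30.0]
  - target_id: Transition_NBD
    conformation: transition
    domain_class: NBD
    pair_group: Transition
    box_center: [0.0, 0.0, -36.0]
    box_size: [52.0, 40.0, 30.0]
  - target_id: Transition_NBD_1
    conformation: transition
    domain_class: NBD
    pair_group: Transition
    box_center: [-14.0, -8.0, -36.0]
    box_size: [28.0, 28.0, 28.0]
  - target_id: Transition_NBD_2
    conformation: transition
    domain_class: NBD
    pair_group: Transition
    box_center: [14.0, 8.0, -36.0]
    box_size: [28.0, 28.0, 28.0]
  - target_id: 3B5X_NBD_1
    conformation: 3B5X_closed_inward
    domain_class: NBD
    pair_group: 3B5X
    box_center: [-10.0, -6.0, -34.0]
    box_size: [28.0, 28.0, 28.0]
  - target_id: 3B5X_NBD_2
    conformation: 3B5X_closed_inward
    domain_class: NBD
    pair_group: 3B5X
    box_center: [10.0, 6.0, -34.0]
    box_size: [28.0, 28.0, 28.0]
  - target_id: 3B5Z_NBD_1
    conformation: 3B5Z_nucleotide_bound
    domain_class: NBD
    box_center: [-12.0, -7.0, -35.0]
    box_size: [28.0, 28.0, 28.0]
  - target_id: 3B5Z_NBD_2
    conformation: 3B5Z_nucleotide_bound
    domain_class: NBD
    box_center: [12.0, 7.0, -35.0]
    box_size: [28.0, 28.0, 28.0]
  - target_id: 2HYD_NBD_1
    conformation: 2HYD_closed_dimer
    domain_class: NBD
    box_center: [-13.0, -7.0, -36.0]
    box_size: [28.0, 28.0, 28.0]
  - target_id: 2HYD_NBD_2
    conformation: 2HYD_closed_dimer
    domain_class: NBD
    box_center: [13.0, 7.0, -36.0]
    box_size: [28.0, 28.0, 28.0]
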