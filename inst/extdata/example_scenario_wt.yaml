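# Example slot-model scenario (synthetic illustration).
# synGAP dissociation constants are the measured values; competitor copy
# numbers and affinities are ILLUSTRATIVE PLACEHOLDERS, not measurements.
psd95_copies: 300.0
genotype: WT
conditions: []
volume_fL: 0.5
haplo_ligand: synGAP
ligands:
- name: synGAP
  copies: 120.0
  kd:
    PDZ1: 220.0
    PDZ2: 1500.0
    PDZ3: 620.0
  modifiers:
    phospho_camkii:
    - 10.0
    phospho_plk2:
    - 2.0
    cam_bound:
      PDZ3: 1.33
- name: TARP
  copies: 150.0
  kd:
    PDZ1: 1000.0
    PDZ2: 1000.0
- name: LRRTM2
  copies: 60.0
  kd:
    PDZ1: 1500.0
    PDZ2: 1500.0
- name: NLG1
  copies: 60.0
  kd:
    PDZ3: 500.0
- name: NLG2
  copies: 40.0
  kd:
    PDZ3: 1000.0
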