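# Composite and paragroup definitions for the packaged fixture phylogeny.
# A composite lists the atomic assignment nodes it unions; a paragroup names
# an ancestor whose subtree carriers are taken minus the subtrees of the
# excluded descendant groups (asterisk suffix by convention).
groups:
  - label: IJ-M429
    members: [I-M170, I1-M253, I2-M223, J-M304, J1-M267, J2-M172]
  - label: R1-P231
    members: [R1a-M420, R1b-M343]
  - label: "F-M89*"
    ancestor: F-M89
    exclude: [GH-F871, IJK-S137]
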