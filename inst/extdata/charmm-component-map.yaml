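# Example component map binding CHARMM-style residue names to the
# component classes used by this package. Head/tail atoms point from the
# carboxyl head to the terminal chain carbon of each fatty acid.
classes:
  LAU: fatty_acid
  MYR: fatty_acid
  PALM: fatty_acid
  STEA: fatty_acid
  TIP3: water
  SOD: ion
  CLA: ion
  POT: ion
  MGH2: ion
  CAL: ion
head_atom:
  LAU: C1
  MYR: C1
  PALM: C1
  STEA: C1
tail_atom:
  LAU: C12
  MYR: C14
  PALM: C16
  STEA: C18
masses:
  LAU: 200.32
  MYR: 228.37
  PALM: 256.42
  STEA: 284.48
  TIP3: 18.015
  SOD: 22.990
  CLA: 35.453
  POT: 39.098
  MGH2: 24.305
  CAL: 40.078
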