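# Per-residue property tables used for physico-chemical delta features.
# charge: formal side-chain charge at pH 7 (His treated as neutral).
# hydrophobicity: Kyte-Doolittle hydropathy index.
# molecular_weight: residue (monomer minus water) mass, Da.
# polarity / aromaticity: binary class membership.
# accessibility: theoretical maximum accessible surface area (Tien et al.
#   2013, A^2) divided by the tryptophan maximum, i.e. normalized to (0, 1].
charge:
  "A": 0
  "R": 1
  "N": 0
  "D": -1
  "C": 0
  "Q": 0
  "E": -1
  "G": 0
  "H": 0
  "I": 0
  "L": 0
  "K": 1
  "M": 0
  "F": 0
  "P": 0
  "S": 0
  "T": 0
  "W": 0
  "Y": 0
  "V": 0
hydrophobicity:
  "A": 1.8
  "R": -4.5
  "N": -3.5
  "D": -3.5
  "C": 2.5
  "Q": -3.5
  "E": -3.5
  "G": -0.4
  "H": -3.2
  "I": 4.5
  "L": 3.8
  "K": -3.9
  "M": 1.9
  "F": 2.8
  "P": -1.6
  "S": -0.8
  "T": -0.7
  "W": -0.9
  "Y": -1.3
  "V": 4.2
molecular_weight:
  "A": 71.08
  "R": 156.19
  "N": 114.10
  "D": 115.09
  "C": 103.14
  "Q": 128.13
  "E": 129.12
  "G": 57.05
  "H": 137.14
  "I": 113.16
  "L": 113.16
  "K": 128.17
  "M": 131.19
  "F": 147.18
  "P": 97.12
  "S": 87.08
  "T": 101.10
  "W": 186.21
  "Y": 163.18
  "V": 99.13
polarity:
  "A": 0
  "R": 1
  "N": 1
  "D": 1
  "C": 1
  "Q": 1
  "E": 1
  "G": 0
  "H": 1
  "I": 0
  "L": 0
  "K": 1
  "M": 0
  "F": 0
  "P": 0
  "S": 1
  "T": 1
  "W": 0
  "Y": 1
  "V": 0
aromaticity:
  "A": 0
  "R": 0
  "N": 0
  "D": 0
  "C": 0
  "Q": 0
  "E": 0
  "G": 0
  "H": 0
  "I": 0
  "L": 0
  "K": 0
  "M": 0
  "F": 1
  "P": 0
  "S": 0
  "T": 0
  "W": 1
  "Y": 1
  "V": 0
accessibility:
  "A": 0.453
  "R": 0.961
  "N": 0.684
  "D": 0.677
  "C": 0.586
  "Q": 0.789
  "E": 0.782
  "G": 0.365
  "H": 0.786
  "I": 0.691
  "L": 0.705
  "K": 0.828
  "M": 0.786
  "F": 0.842
  "P": 0.558
  "S": 0.544
  "T": 0.604
  "W": 1.000
  "Y": 0.923
  "V": 0.611
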