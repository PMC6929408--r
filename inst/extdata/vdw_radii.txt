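# Element-keyed van der Waals radii (Angstrom) used to decide whether a
# lattice point lies inside a protein. These are a documented stand-in set
# in the range conventional for docking grids; supply your own two-column
# file (element radius) to substitute. DEFAULT covers unknown elements.
C 1.9
N 1.7
O 1.6
S 2.0
H 1.2
P 2.1
DEFAULT 1.8
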