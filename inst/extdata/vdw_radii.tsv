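# United heavy-atom van der Waals radii, version united-heavy-1.0
# Element-class radii in Angstrom for protein heavy atoms with implicit
# hydrogens (Chothia 1976-style united-atom values). Frames analysed by
# this package carry no hydrogens, so carbon radii absorb bonded H.
element	radius_A
C	1.87
N	1.65
O	1.40
S	1.85
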