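name,C,H,O,N,S,P
H2,0,2,0,0,0,0
CH2,1,2,0,0,0,0
O,0,0,1,0,0,0
NH3,0,3,0,1,0,0
H2O,0,2,1,0,0,0
CO,1,0,1,0,0,0
CH2O,1,2,1,0,0,0
C2H2O,2,2,1,0,0,0
CO2,1,0,2,0,0,0
HPO3,0,1,3,0,0,1
SO3,0,0,3,0,1,0
glucose_C6H10O5,6,10,5,0,0,0
glycine_residue,2,3,1,1,0,0
alanine_residue,3,5,1,1,0,0
serine_residue,3,5,2,1,0,0
proline_residue,5,7,1,1,0,0
valine_residue,5,9,1,1,0,0
threonine_residue,4,7,2,1,0,0
cysteine_residue,3,5,1,1,1,0
leucine_isoleucine_residue,6,11,1,1,0,0
asparagine_residue,4,6,2,2,0,0
aspartate_residue,4,5,3,1,0,0
glutamine_residue,5,8,2,2,0,0
lysine_residue,6,12,1,2,0,0
glutamate_residue,5,7,3,1,0,0
methionine_residue,5,9,1,1,1,0
histidine_residue,6,7,1,3,0,0
phenylalanine_residue,9,9,1,1,0,0
arginine_residue,6,12,1,4,0,0
tyrosine_residue,9,9,2,1,0,0
tryptophan_residue,11,10,1,2,0,0
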