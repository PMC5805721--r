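name,d_c,d_h,d_n,d_o,d_p,d_s,n_kind
glycine,2,3,1,1,0,0,organic
alanine,3,5,1,1,0,0,organic
serine,3,5,1,2,0,0,organic
proline,5,7,1,1,0,0,organic
valine,5,9,1,1,0,0,organic
threonine,4,7,1,2,0,0,organic
cysteine,3,5,1,1,0,1,organic
leucine,6,11,1,1,0,0,organic
isoleucine,6,11,1,1,0,0,organic
asparagine,4,6,2,2,0,0,organic
aspartic_acid,4,5,1,3,0,0,organic
glutamine,5,8,2,2,0,0,organic
lysine,6,12,2,1,0,0,organic
glutamic_acid,5,7,1,3,0,0,organic
methionine,5,9,1,1,0,1,organic
histidine,6,7,3,1,0,0,organic
phenylalanine,9,9,1,1,0,0,organic
arginine,6,12,4,1,0,0,organic
tyrosine,9,9,1,2,0,0,organic
tryptophan,11,10,2,1,0,0,organic
adenine,5,5,5,0,0,0,organic
guanine,5,5,5,1,0,0,organic
cytosine,4,5,3,1,0,0,organic
uracil,4,4,2,2,0,0,organic
thymine,5,6,2,2,0,0,organic
glycosyl_hexose,6,10,0,5,0,0,none
glycosyl_pentose,5,8,0,4,0,0,none
glycosyl_deoxyhexose,6,10,0,4,0,0,none
glycosyl_glucuronic_acid,6,8,0,6,0,0,none
glycosyl_hexosamine,6,11,1,4,0,0,organic
glycosyl_n_acetylhexosamine,8,13,1,5,0,0,organic
glucose,6,12,0,6,0,0,none
hydrogenation_h2,0,2,0,0,0,0,none
hydration_h2o,0,2,0,1,0,0,none
methylene_ch2,1,2,0,0,0,0,none
oxygenation_o,0,0,0,1,0,0,none
carbonylation_co,1,0,0,1,0,0,none
carboxylation_co2,1,0,0,2,0,0,none
formaldehyde_ch2o,1,2,0,1,0,0,none
formic_acid_ch2o2,1,2,0,2,0,0,none
acetylation_c2h2o,2,2,0,1,0,0,none
acetic_acid_c2h4o2,2,4,0,2,0,0,none
propionic_acid,3,6,0,2,0,0,none
acrylic_acid,3,4,0,2,0,0,none
ethene_c2h4,2,4,0,0,0,0,none
ethyne_c2h2,2,2,0,0,0,0,none
propene_c3h6,3,6,0,0,0,0,none
isoprene_c5h8,5,8,0,0,0,0,none
pyruvic_acid,3,4,0,3,0,0,none
lactic_acid,3,6,0,3,0,0,none
glyoxylic_acid,2,2,0,3,0,0,none
glycerol,3,8,0,3,0,0,none
malonic_acid,3,4,0,4,0,0,none
fumaric_acid,4,4,0,4,0,0,none
succinic_acid,4,6,0,4,0,0,none
malic_acid,4,6,0,5,0,0,none
oxaloacetic_acid,4,4,0,5,0,0,none
ketoglutaric_acid,5,6,0,5,0,0,none
citric_acid,6,8,0,7,0,0,none
benzoic_acid,7,6,0,2,0,0,none
acetone,3,6,0,1,0,0,none
ethanol,2,6,0,1,0,0,none
acetamide,2,5,1,1,0,0,organic
methylamine,1,5,1,0,0,0,organic
ethanolamine,2,7,1,1,0,0,organic
urea,1,4,2,1,0,0,organic
ammonia_nh3,0,3,1,0,0,0,inorganic
nitrous_acid_hno2,0,1,1,2,0,0,inorganic
nitric_acid_hno3,0,1,1,3,0,0,inorganic
hydrogen_cyanide_hcn,1,1,1,0,0,0,inorganic
hydrogen_sulfide_h2s,0,2,0,0,0,1,none
sulfur_s,0,0,0,0,0,1,none
sulfur_dioxide_so2,0,0,0,2,0,1,none
sulfonation_so3,0,0,0,3,0,1,none
sulfuric_acid_h2so4,0,2,0,4,0,1,none
phosphorylation_hpo3,0,1,0,3,1,0,none
phosphoric_acid_h3po4,0,3,0,4,1,0,none
biotinyl,10,14,2,2,0,1,organic
glutathionyl,10,15,3,5,0,1,organic
taurine,2,7,1,3,0,1,organic
putrescine,4,12,2,0,0,0,organic
ornithine_residue,5,10,2,1,0,0,organic
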