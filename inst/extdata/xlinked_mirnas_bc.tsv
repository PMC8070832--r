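# X chromosome-located miRNAs with reported breast-cancer association.
# age_associated = 1 marks miRNAs differentially expressed between female
# age groups. Extend or replace with your own curated list as needed.
mirna	bc_related	age_associated
hsa-mir-18b	1	0
hsa-mir-221	1	0
hsa-mir-224	1	0
hsa-mir-502	1	1
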