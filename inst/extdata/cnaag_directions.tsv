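gene_id	direction_le	direction_ob
ATP12A	up	up
C1orf127	up	up
DEFA1	up	up
DEFA1B	up	up
ELANE	up	up
IL20	up	up
PTX4	up	up
RND1	up	up
STK32A	up	up
ANGPTL7	up	down
EMCN	up	down
ICOS	down	up
INHBB	up	down
OR7D2	down	up
PCSK1	down	up
RBP4	up	down
SMIM10L2A	up	down
UPK1B	up	down
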