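compound	dfG_prime_kJ_per_mol	source
replicator	-30	toy
CO2	-394	toy
dithiol	100	toy
disulfide	-10	toy
ammonia	-16	toy
thiyl	50	toy
water	-237	toy
proton	0	toy
coa-thiol	-50	toy
carboxy-replicator	-420	toy
formyl-replicator	-150	toy
amino-replicator	-90	toy
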