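pathway	status	steps	atp	cofactors	carbons	ref
CETCH	synthetic	11	1	4	2	Schwander et al. 2016
rGPS-MCG	synthetic	18	4	6	3	Luo et al. 2022
C4-glyoxylate/alanine	theoretical	9	2	2	2	Bar-Even et al. 2010
rTCA	natural	12	4	7	4	Evans et al. 1966
3HP/4HB	natural	16	4	6	2	Berg et al. 2007
DC/4HB	natural	14	4	7	2	Huber et al. 2008
3HP-bicycle	natural	19	3	4	2	Zarzycki et al. 2009
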