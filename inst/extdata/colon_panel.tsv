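lipid_class	carbons	double_bonds
PC	32	0
PC	34	1
PC	34	2
PC	36	1
PC	36	2
PC	36	3
PC	36	4
PC	38	4
SM	34	1
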