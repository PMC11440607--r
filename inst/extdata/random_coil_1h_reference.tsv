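residue_number	residue_name	atom_name	shift_ppm
21	LEU	HA	4.34
25	TRP	HA	4.66
25	TRP	HE1	10.22
30	GLY	HA2	3.96
30	GLY	HA3	3.96
31	PRO	HA	4.42
31	PRO	HB2	2.05
35	ARG	HA	4.35
37	PRO	HA	4.42
37	PRO	HB2	2.05
38	PRO	HD1	3.65
38	PRO	HD2	3.65
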