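# The 16 missense novelties of the bundled cohort with the original and
# novel residues, their basic-property categories, and the assigned
# four-criterion "+" score with its constituent criteria.
allele	codon_position	ref_aa	ref_property	alt_aa	alt_property	score	aa_change	property_change	binding_site	eplet_effect
A*03:452	144	Lys	basic	Gln	polar_uncharged	++++	1	1	1	1
A*26:203	-15	Val	nonpolar_aliphatic	Leu	nonpolar_aliphatic	+	1	0	0	0
B*15:675	-9	Ala	nonpolar_aliphatic	Val	nonpolar_aliphatic	+	1	0	0	0
B*48:55	228	Thr	polar_uncharged	Ala	nonpolar_aliphatic	++	1	1	0	0
B*56:88	116	Leu	nonpolar_aliphatic	Phe	nonpolar_aromatic	++++	1	1	1	1
C*05:277	340	Cys	polar_uncharged	Ser	polar_uncharged	+	1	0	0	0
C*07:1041	17	Arg	basic	Ser	polar_uncharged	++++	1	1	1	1
C*07:1043	60	Trp	nonpolar_aromatic	Gly	nonpolar_aliphatic	+++	1	1	1	0
DPA1*01:106	-30	Arg	basic	His	basic	+	1	0	0	0
DPA1*01:136	149	His	basic	Arg	basic	+	1	0	0	0
DPA1*01:60	224	Arg	basic	Trp	nonpolar_aromatic	++	1	1	0	0
DPA1*02:96	213	Ile	nonpolar_aliphatic	Phe	nonpolar_aromatic	++	1	1	0	0
DPB1*1088:01	194	Gln	polar_uncharged	Arg	basic	++	1	1	0	0
DRB1*14:249	6	Arg	basic	Cys	polar_uncharged	++++	1	1	1	1
DRB5*01:130	160	Met	nonpolar_aliphatic	Ile	nonpolar_aliphatic	+	1	0	0	0
DRB5*02:37	150	Asn	polar_uncharged	Ser	polar_uncharged	+	1	0	0	0
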