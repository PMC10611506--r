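# SYNTHETIC miniature eplet registry. Covers the eplet-affecting positions
# of the bundled cohort plus decoy entries; it is a stand-in for testing and
# demonstration, NOT a copy of the HLA Eplet Registry. Constituents are
# position:residue tokens in mature-protein numbering (one-letter residues).
name	locus_group	constituents
144K	ABC	144:K
116F	ABC	116:F
17S	ABC	17:S
6C	DRB	6:C
45EV	ABC	45:E,46:V
62GE	ABC	62:G,63:E
228K	ABC	228:K
71K	DRB	71:K
52PQ	DQ	52:P,53:Q
84DEAV	DP	84:D,85:E,86:A,87:V
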