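# The 29 unique novel alleles of the bundled 18-month detection cohort:
# locus, HLA class, mutation type, exon, protein location, nucleotide change
# and genomic position as reported. Genomic positions are carried as opaque
# annotations (reference coordinate system not reproduced here).
# ref_codon/alt_codon are the codon change; for silent rows (where only the
# nucleotide change was reported) the codons are RECONSTRUCTED to be
# consistent with the base change. codon_position is mature-protein
# numbering (NA where not reported).
allele	locus	hla_class	mutation_type	exon	protein_location	ref_base	alt_base	genomic_position	codon_position	ref_codon	alt_codon
A*03:452	HLA-A	class_I	missense	3	Antigen-binding site, alpha2	A	C	873	144	AAA	CAA
A*26:203	HLA-A	class_I	missense	1	Leader peptide	G	C	28	-15	GTG	CTG
B*15:675	HLA-B	class_I	missense	1	Leader peptide	C	T	47	-9	GCC	GTC
B*48:01:12	HLA-B	class_I	silent	3	Antigen-binding site, alpha2	C	T	736	NA	ACC	ACT
B*48:55	HLA-B	class_I	missense	4	alpha3 extracellular arm	A	G	1701	228	ACT	GCT
B*56:88	HLA-B	class_I	missense	3	Antigen-binding site, alpha2	A	C	793	116	TTA	TTC
C*05:277	HLA-C	class_I	missense	7	Cytoplasmic tail	G	C	2721	340	TGC	TCC
C*07:1041	HLA-C	class_I	missense	2	Antigen-binding site, alpha1	C	A	256	17	CGC	AGC
C*07:1043	HLA-C	class_I	missense	2	Antigen-binding site, alpha1	T	G	385	60	TGG	GGG
DPA1*01:03:38:02	HLA-DPA1	class_II_alpha	silent	1	Leader peptide	C	T	51	NA	GCC	GCT
DPA1*01:03:45	HLA-DPA1	class_II_alpha	silent	3	alpha2 extracellular arm	C	T	4506	NA	GCC	GCT
DPA1*01:106	HLA-DPA1	class_II_alpha	missense	1	Leader peptide	G	A	5	-30	CGC	CAC
DPA1*01:136	HLA-DPA1	class_II_alpha	missense	3	alpha2 extracellular arm	A	G	4463	149	CAT	CGT
DPA1*01:137N	HLA-DPA1	class_II_alpha	nonsense	1	Leader peptide	C	T	79	-5	CGA	TGA
DPA1*01:60	HLA-DPA1	class_II_alpha	missense	4	Transmembrane/cytoplasmic tail	C	T	4901	224	CGG	TGG
DPA1*02:02:13	HLA-DPA1	class_II_alpha	silent	4	Transmembrane/cytoplasmic tail	T	C	4876	NA	GGT	GGC
DPA1*02:96	HLA-DPA1	class_II_alpha	missense	4	Transmembrane/cytoplasmic tail	A	T	4850	213	ATT	TTT
DPB1*1088:01	HLA-DPB1	class_II_beta	missense	4	Transmembrane	A	G	9701	194	CAA	CGA
DQA1*01:01:09:02	HLA-DQA1	class_II_alpha	silent	1	Leader peptide	C	G	36	NA	CTC	CTG
DQA1*01:02:15	HLA-DQA1	class_II_alpha	silent	1	Leader peptide	C	T	48	NA	TCC	TCT
DQA1*01:02:16	HLA-DQA1	class_II_alpha	silent	2	Antigen-binding site, alpha1	C	A	3976	NA	CGC	CGA
DQA1*01:04:08	HLA-DQA1	class_II_alpha	silent	3	alpha2 extracellular arm	C	T	4548	NA	CTA	TTA
DQA1*02:01:15Q	HLA-DQA1	class_II_alpha	silent	2	Antigen-binding site, alpha1	C	T	3809	NA	CTG	TTG
DQA1*04:01:07	HLA-DQA1	class_II_alpha	silent	1	Leader peptide	C	T	48	NA	GGC	GGT
DQA1*05:05:16	HLA-DQA1	class_II_alpha	silent	1	Leader peptide	T	A	69	NA	GGT	GGA
DRB1*14:249	HLA-DRB1	class_II_beta	missense	2	Antigen-binding site, beta1	C	T	8091	6	CGC	TGC
DRB1*14:54:12	HLA-DRB1	class_II_beta	silent	3	beta2 extracellular arm	A	G	10752	NA	CCA	CCG
DRB5*01:130	HLA-DRB5	class_II_beta	missense	3	beta2 extracellular arm	G	T	10808	160	ATG	ATT
DRB5*02:37	HLA-DRB5	class_II_beta	missense	3	beta2 extracellular arm	A	G	10732	150	AAT	AGT
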