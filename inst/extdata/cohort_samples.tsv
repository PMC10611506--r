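# RECONSTRUCTED sample-level table of the bundled cohort: 41 samples carrying
# the 29 unique novel alleles. Per-sample patient-category and ethnicity
# assignments are reconstructed to match the reported marginals (11/9/3/17/1
# across categories; ethnicity rounding to 51/32/12/2/2 percent) and the
# narrated family clusters (DQA1*01:01:09:02 in 7 samples, DQA1*05:05:16 in
# 2); they are not the original per-sample assignments.
sample_id	allele	patient_category	ethnicity	specimen
VGH001	A*03:452	solid_organ_patient	API	peripheral_blood
VGH002	B*48:55	solid_organ_donor	API	peripheral_blood
VGH003	A*26:203	hsct_donor	API	peripheral_blood
VGH004	B*15:675	disease_association	CAU	peripheral_blood
VGH005	B*48:01:12	hsct_donor	CAU	peripheral_blood
VGH006	C*05:277	solid_organ_patient	API	peripheral_blood
VGH007	C*07:1041	solid_organ_donor	API	peripheral_blood
VGH008	C*07:1043	hsct_donor	CAU	peripheral_blood
VGH009	DPA1*01:03:38:02	solid_organ_patient	API	peripheral_blood
VGH010	DPA1*01:03:38:02	solid_organ_donor	API	peripheral_blood
VGH011	DPA1*01:03:45	solid_organ_patient	CAU	peripheral_blood
VGH012	DPA1*01:106	solid_organ_donor	API	peripheral_blood
VGH013	DPA1*01:136	solid_organ_patient	CAU	peripheral_blood
VGH014	DPA1*01:137N	hsct_patient	API	peripheral_blood
VGH015	DPA1*01:60	hsct_donor	CAU	peripheral_blood
VGH016	DPA1*02:02:13	solid_organ_patient	API	peripheral_blood
VGH017	DPA1*02:02:13	solid_organ_donor	API	peripheral_blood
VGH018	DPA1*02:02:13	hsct_donor	NAM	peripheral_blood
VGH019	DPA1*02:96	hsct_donor	API	peripheral_blood
VGH020	DPB1*1088:01	hsct_donor	CAU	peripheral_blood
VGH021	DQA1*01:02:15	solid_organ_patient	CAU	peripheral_blood
VGH022	DQA1*01:02:15	solid_organ_donor	CAU	peripheral_blood
VGH023	DQA1*01:02:16	solid_organ_patient	API	peripheral_blood
VGH024	DQA1*01:04:08	hsct_donor	NAM	peripheral_blood
VGH026	DQA1*02:01:15Q	solid_organ_patient	NAM	peripheral_blood
VGH027	DQA1*04:01:07	solid_organ_donor	NAM	peripheral_blood
VGH028	DQA1*04:01:07	hsct_donor	NAM	peripheral_blood
VGH029	B*56:88	hsct_patient	API	peripheral_blood
VGH030	DRB1*14:249	hsct_donor	HIS	peripheral_blood
VGH031	DQA1*01:01:09:02	hsct_patient	API	peripheral_blood
VGH032	DQA1*01:01:09:02	hsct_donor	API	peripheral_blood
VGH033	DQA1*01:01:09:02	hsct_donor	API	peripheral_blood
VGH034	DQA1*01:01:09:02	hsct_donor	API	peripheral_blood
VGH035	DQA1*01:01:09:02	hsct_donor	API	peripheral_blood
VGH036	DQA1*01:01:09:02	hsct_donor	CAU	peripheral_blood
VGH037	DQA1*01:01:09:02	solid_organ_patient	CAU	peripheral_blood
VGH038	DQA1*05:05:16	solid_organ_patient	API	peripheral_blood
VGH039	DQA1*05:05:16	solid_organ_donor	API	peripheral_blood
VGH040	DRB1*14:54:12	solid_organ_donor	CAU	peripheral_blood
VGH041	DRB5*01:130	hsct_donor	CAU	peripheral_blood
VGH042	DRB5*02:37	hsct_donor	AFA	peripheral_blood
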