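family_id	relative_id	relation	lineage	diagnosis	age_at_diagnosis	known_at_proband_diagnosis	verification	malignant	consanguineous	known_cps
C1	C1_gf_m	grandparent	maternal	chronic lymphoblastic leukemia	62	TRUE	verified	TRUE	FALSE	FALSE
F1	F1_gf_m	grandparent	maternal	lymphoma	68	TRUE	verified	TRUE	FALSE	FALSE
E4	E4_gf_m	grandparent	maternal	colon cancer	84	TRUE	verified	TRUE	FALSE	FALSE
H2	H2_fa	father	not_applicable	retinoblastoma	0	TRUE	verified	TRUE	FALSE	FALSE
H2	H2_aunt_p	parent_sibling	paternal	retinoblastoma	0	TRUE	verified	TRUE	FALSE	FALSE
H2	H2_aunt_p	parent_sibling	paternal	rhabdomyosarcoma	14	TRUE	verified	TRUE	FALSE	FALSE
H2	H2_aunt_p	parent_sibling	paternal	melanoma	20	TRUE	verified	TRUE	FALSE	FALSE
H2	H2_gf_p	grandparent	paternal	melanoma	39	TRUE	verified	TRUE	FALSE	FALSE
H2	H2_gf_p	grandparent	paternal	myelofibrosis	48	TRUE	verified	TRUE	FALSE	FALSE
A1	A1_fa	father	not_applicable	pheochromocytoma	34	FALSE	verified	TRUE	FALSE	FALSE
A1	A1_gm_p	grandparent	paternal	hepatic cholangiocarcinoma	36	TRUE	verified	TRUE	FALSE	FALSE
A2	A2_gf_p	grandparent	paternal	colon cancer	84	TRUE	verified	TRUE	FALSE	FALSE
J1	J1_gf_m	grandparent	maternal	urothelial carcinoma	71	TRUE	verified	TRUE	FALSE	FALSE
K1	K1_gf_p	grandparent	paternal	lung cancer	71	TRUE	verified	TRUE	FALSE	FALSE
K1	K1_gf_m	grandparent	maternal	lung cancer	79	TRUE	verified	TRUE	FALSE	FALSE
I1	I1_gm_m	grandparent	maternal	lung cancer	64	TRUE	verified	TRUE	FALSE	FALSE
I1	I1_uncle_m	parent_sibling	maternal	urothelial carcinoma	41	TRUE	verified	TRUE	FALSE	FALSE
L1	L1_gm_p	grandparent	paternal	lung cancer	50	TRUE	verified	TRUE	FALSE	FALSE
L2	L2_gm_p	grandparent	paternal	lung cancer	50	TRUE	verified	TRUE	FALSE	FALSE
L3	L3_gm_m	grandparent	maternal	ovarian cancer	68	TRUE	verified	TRUE	FALSE	FALSE
L3	L3_gm_p	grandparent	paternal	gastrointestinal stromal tumor	82	TRUE	verified	TRUE	FALSE	FALSE
L4	L4_aunt_m	parent_sibling	maternal	melanoma	37	TRUE	verified	TRUE	FALSE	FALSE
Q2	Q2_gm_p	grandparent	paternal	urothelial carcinoma	74	TRUE	verified	TRUE	FALSE	FALSE
R1	R1_uncle_m	parent_sibling	maternal	tumor on heart valve	0	TRUE	verified	FALSE	FALSE	FALSE
N2	N2_gf_p	grandparent	paternal	esophageal cancer	59	TRUE	verified	TRUE	FALSE	FALSE
N1	N1_gm_m	grandparent	maternal	breast cancer	63	TRUE	verified	TRUE	FALSE	FALSE
O1	O1_gf_p	grandparent	paternal	prostate cancer	65	TRUE	verified	TRUE	FALSE	FALSE
O1	O1_gm_p	grandparent	paternal	cervical cancer	54	TRUE	verified	TRUE	FALSE	FALSE
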