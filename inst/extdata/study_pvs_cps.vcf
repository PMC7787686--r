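##fileformat=VCFv4.2
##source=cpsscreen
##INFO=<ID=PATIENT,Number=1,Type=String,Description="Proband carrying the call">
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Sequence Ontology consequence">
##INFO=<ID=GNOMAD_AF_MAX,Number=1,Type=Float,Description="Max allele frequency in any large gnomAD population">
##INFO=<ID=CADD_PHRED,Number=1,Type=Float,Description="CADD-PHRED score">
##INFO=<ID=SPLICE_DELTAS,Number=1,Type=String,Description="Comma list of fractional splice-program score changes">
##INFO=<ID=CRYPTIC,Number=1,Type=Integer,Description="Strong cryptic splice site generated (0/1)">
##INFO=<ID=ACMG_CLASS,Number=1,Type=Integer,Description="Curated ACMG class 1-5">
##INFO=<ID=INHERIT,Number=1,Type=String,Description="maternal/paternal/de_novo/unknown">
##INFO=<ID=EVENT,Number=1,Type=String,Description="Chromosomal event tag for symbolic records">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
##FORMAT=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	CALL
1	193091100	.	C	T	.	PASS	PATIENT=C1;GENE=CDC73;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=37;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
5	176939300	.	C	T	.	PASS	PATIENT=G1;GENE=DDX41;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=31;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=maternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
5	176939350	.	G	C	.	PASS	PATIENT=G1;GENE=DDX41;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=32;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=paternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
22	21344500	.	C	T	.	PASS	PATIENT=F1;GENE=LZTR1;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=38;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	29653200	.	C	T	.	PASS	PATIENT=E3;GENE=NF1;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=38;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=maternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	29490320	.	CG	C	.	PASS	PATIENT=E1;GENE=NF1;CSQ=splice_donor_variant;GNOMAD_AF_MAX=.;CADD_PHRED=34;SPLICE_DELTAS=-0.45,-0.38,-0.52,-0.12;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	29421945	.	N	<DEL>	.	PASS	PATIENT=E2;GENE=NF1;CSQ=feature_truncation;GNOMAD_AF_MAX=.;CADD_PHRED=.;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=maternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	29556000	.	C	CC	.	PASS	PATIENT=E4;GENE=NF1;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=34;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
13	48941648	.	C	T	.	PASS	PATIENT=H1;GENE=RB1;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=36;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
13	48916800	.	AGAAA	A	.	PASS	PATIENT=H2;GENE=RB1;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=36;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=paternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
13	48878100	.	CAG	C	.	PASS	PATIENT=H3;GENE=RB1;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=31;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=de_novo;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
13	48951060	.	T	C	.	PASS	PATIENT=H4;GENE=RB1;CSQ=splice_donor_variant;GNOMAD_AF_MAX=.;CADD_PHRED=25.2;SPLICE_DELTAS=-0.45,-0.38,-0.52,-0.12;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
1	161298257	.	C	T	.	PASS	PATIENT=B1;GENE=SDHC;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=34;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
19	11130000	.	N	<DEL>	.	PASS	PATIENT=K1;GENE=SMARCA4;CSQ=feature_truncation;GNOMAD_AF_MAX=.;CADD_PHRED=.;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	7577120	.	G	C	.	PASS	PATIENT=A1;GENE=TP53;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=28.4;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=paternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	7577121	.	C	T	.	PASS	PATIENT=A2;GENE=TP53;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=27.3;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=de_novo;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
16	2130000	.	C	CC	.	PASS	PATIENT=J1;GENE=TSC2;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=23.5;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=de_novo;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
21	1	.	N	<DUP>	.	PASS	PATIENT=L1;GENE=.;CSQ=copy_number_gain;GNOMAD_AF_MAX=.;CADD_PHRED=.;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=trisomy_21	GT:DP:GQ:VAF	0/1:34:99:0.48
21	1	.	N	<DUP>	.	PASS	PATIENT=L2;GENE=.;CSQ=copy_number_gain;GNOMAD_AF_MAX=.;CADD_PHRED=.;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=trisomy_21	GT:DP:GQ:VAF	0/1:34:99:0.48
21	1	.	N	<DUP>	.	PASS	PATIENT=L3;GENE=.;CSQ=copy_number_gain;GNOMAD_AF_MAX=.;CADD_PHRED=.;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=trisomy_21	GT:DP:GQ:VAF	0/1:34:99:0.48
21	1	.	N	<DUP>	.	PASS	PATIENT=L4;GENE=.;CSQ=copy_number_gain;GNOMAD_AF_MAX=.;CADD_PHRED=.;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=trisomy_21	GT:DP:GQ:VAF	0/1:34:99:0.48
5	112175211	.	T	A	.	PASS	PATIENT=Q2;GENE=APC;CSQ=missense_variant;GNOMAD_AF_MAX=0.003;CADD_PHRED=5.3;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
5	112175211	.	T	A	.	PASS	PATIENT=Q1;GENE=APC;CSQ=missense_variant;GNOMAD_AF_MAX=0.003;CADD_PHRED=5.3;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
11	108196003	.	G	C	.	PASS	PATIENT=R1;GENE=ATM;CSQ=missense_variant;GNOMAD_AF_MAX=1e-04;CADD_PHRED=32;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
2	215591264	.	N	<DEL>	.	PASS	PATIENT=S1;GENE=BARD1;CSQ=feature_truncation;GNOMAD_AF_MAX=.;CADD_PHRED=.;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
13	32914000	.	ACT	A	.	PASS	PATIENT=N2;GENE=BRCA2;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=21.2;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=maternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	63533000	.	C	T	.	PASS	PATIENT=N2;GENE=AXIN2;CSQ=splice_donor_variant;GNOMAD_AF_MAX=.;CADD_PHRED=24.5;SPLICE_DELTAS=-0.45,-0.38,-0.52,-0.12;CRYPTIC=0;ACMG_CLASS=4;INHERIT=maternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
13	32920000	.	GACAA	G	.	PASS	PATIENT=N1;GENE=BRCA2;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=29.1;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
22	29091857	.	TC	T	.	PASS	PATIENT=O1;GENE=CHEK2;CSQ=frameshift_variant;GNOMAD_AF_MAX=0.012;CADD_PHRED=35;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
1	45797228	.	T	C	.	PASS	PATIENT=M1;GENE=MUTYH;CSQ=missense_variant;GNOMAD_AF_MAX=0.0015;CADD_PHRED=24.7;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
16	23635000	.	C	T	.	PASS	PATIENT=E2;GENE=PALB2;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=41;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=paternal;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
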