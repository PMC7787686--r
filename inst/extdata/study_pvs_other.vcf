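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
20	43280216	.	C	T	.	PASS	PATIENT=U01;GENE=ADA;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=28;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
20	43280100	.	A	T	.	PASS	PATIENT=U02;GENE=ADA;CSQ=splice_donor_variant;GNOMAD_AF_MAX=.;CADD_PHRED=22.9;SPLICE_DELTAS=-0.45,-0.38,-0.52,-0.12;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
3	142274740	.	T	TA	.	PASS	PATIENT=U03;GENE=ATR;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=20.1;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
15	82422500	.	T	C	.	PASS	PATIENT=U04;GENE=EFL1;CSQ=splice_region_variant;GNOMAD_AF_MAX=.;CADD_PHRED=14.8;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
15	82440000	.	GCC	G	.	PASS	PATIENT=U05;GENE=EFL1;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=15.9;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
2	128050000	.	A	AAGCAGT	.	PASS	PATIENT=S1;GENE=ERCC3;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=37;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
16	89836300	.	G	A	.	PASS	PATIENT=U06;GENE=FANCA;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=17.3;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
16	89838000	.	T	C	.	PASS	PATIENT=U07;GENE=FANCA;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=23.5;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
9	97912300	.	G	A	.	PASS	PATIENT=U08;GENE=FANCC;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=35;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
6	35423800	.	CG	C	.	PASS	PATIENT=U09;GENE=FANCE;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=16.7;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
15	89792100	.	A	G	.	PASS	PATIENT=U10;GENE=FANCI;CSQ=splice_region_variant;GNOMAD_AF_MAX=.;CADD_PHRED=12.7;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
2	58386928	.	C	T	.	PASS	PATIENT=U11;GENE=FANCL;CSQ=splice_donor_variant;GNOMAD_AF_MAX=.;CADD_PHRED=23.3;SPLICE_DELTAS=-0.45,-0.38,-0.52,-0.12;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
2	58388500	.	CTAT	C	.	PASS	PATIENT=U12;GENE=FANCL;CSQ=inframe_deletion;GNOMAD_AF_MAX=.;CADD_PHRED=23.5;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
2	58390000	.	A	AATTA	.	PASS	PATIENT=U13;GENE=FANCL;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=35;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
14	45605000	.	G	C	.	PASS	PATIENT=U01;GENE=FANCM;CSQ=splice_donor_variant;GNOMAD_AF_MAX=.;CADD_PHRED=25.9;SPLICE_DELTAS=-0.45,-0.38,-0.52,-0.12;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
14	45642000	.	GAACCA	G	.	PASS	PATIENT=U14;GENE=FANCM;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=36;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
8	90983440	.	CTT	C	.	PASS	PATIENT=G1;GENE=NBN;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=25.6;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
8	90990000	.	C	CA	.	PASS	PATIENT=U15;GENE=NBN;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=37;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
6	43544000	.	GCA	G	.	PASS	PATIENT=L4;GENE=POLH;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=40;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
6	43550000	.	N	<DEL>	.	PASS	PATIENT=U16;GENE=POLH;CSQ=feature_truncation;GNOMAD_AF_MAX=.;CADD_PHRED=.;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
12	21621900	.	G	C	.	PASS	PATIENT=U17;GENE=RECQL;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=38;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
12	21621900	.	G	C	.	PASS	PATIENT=U18;GENE=RECQL;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=38;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
8	145738000	.	TA	T	.	PASS	PATIENT=U19;GENE=RECQL4;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=21.7;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
7	105172000	.	A	G	.	PASS	PATIENT=U20;GENE=RINT1;CSQ=splice_region_variant;GNOMAD_AF_MAX=.;CADD_PHRED=15.4;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	16843000	.	G	C	.	PASS	PATIENT=U21;GENE=TNFRSF13B;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=35;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	7591000	.	C	T	.	PASS	PATIENT=U22;GENE=WRAP53;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=34;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
17	7591000	.	C	T	.	PASS	PATIENT=U23;GENE=WRAP53;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=34;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
3	14186000	.	GC	G	.	PASS	PATIENT=E3;GENE=XPC;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=26.6;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
2	21232000	.	GC	G	.	PASS	PATIENT=V01;GENE=APOB;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=33;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
19	11216000	.	G	A	.	PASS	PATIENT=V02;GENE=LDLR;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=28;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
12	32945000	.	TG	T	.	PASS	PATIENT=V03;GENE=PKP2;CSQ=frameshift_variant;GNOMAD_AF_MAX=.;CADD_PHRED=34;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
18	28660000	.	C	T	.	PASS	PATIENT=V04;GENE=DSC2;CSQ=splice_region_variant;GNOMAD_AF_MAX=.;CADD_PHRED=22;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
18	29122000	.	G	A	.	PASS	PATIENT=V05;GENE=DSG2;CSQ=stop_gained;GNOMAD_AF_MAX=.;CADD_PHRED=38;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=5;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
11	2593000	.	C	T	.	PASS	PATIENT=V06;GENE=KCNQ1;CSQ=missense_variant;GNOMAD_AF_MAX=.;CADD_PHRED=24;SPLICE_DELTAS=.;CRYPTIC=0;ACMG_CLASS=4;INHERIT=unknown;EVENT=.	GT:DP:GQ:VAF	0/1:34:99:0.48
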