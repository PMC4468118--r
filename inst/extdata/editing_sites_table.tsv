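gene	position	strand	codon_from	codon_to	codon_position	aa_from	aa_to	level_percent
ndhC	13922	+	UCA	UUA	2	S	L	84
rps14	26562	+	UCA	UUA	2	S	L	97
rpoB	37461	+	UCU	UUU	2	S	F	59
rpoB	37674	+	UCA	UUA	2	S	L	68
rpoB	37689	+	UCG	UUG	2	S	L	80
rpoB	39123	+	UCU	UUU	2	S	F	73
rpoC1	40403	+	UCA	UUA	2	S	L	84
rpoC1	41679	+	UCA	UUA	2	S	L	67
rps2	47981	+	ACA	AUA	2	T	I	97
rps2	48095	+	UCA	UUA	2	S	L	97
atpF	51307	+	CCA	CUA	2	P	L	98
atpA	53350	+	UCC	UCU	3	S	S	6
accD	59680	+	UCG	UUG	2	S	L	96
psaI	60699	+	CAU	UAU	1	H	Y	91
psbF	64845	-	UCU	UUU	2	S	F	96
psbE	64969	-	CCU	UCU	1	P	S	98
petL	66108	+	CCC	CUC	2	P	L	57
rps18	68155	+	UCG	UUG	2	S	L	82
intergenic	68964	+	NA	NA	NA	NA	NA	27
clpP	70022	-	CAU	UAU	1	H	Y	90
psbN	74413	-	UCU	UUU	2	S	F	31
petB	76357	+	UCA	UUA	2	S	L	98
rpoA	78836	-	UCA	UUA	2	S	L	35
rpl23	83522	-	UCA	UUA	2	S	L	74
ndhB	92403	-	CCA	CUA	2	P	L	89
ndhB	92629	-	CAU	UAU	1	H	Y	95
ndhB	92772	-	UCA	UUA	2	S	L	93
ndhB	93048	-	UCA	UUA	2	S	L	84
ndhB	93054	-	UCA	UUA	2	S	L	68
ndhB	93830	-	UCU	UUU	2	S	F	92
ndhB	93839	-	CCA	CUA	2	P	L	84
ndhB	93990	-	CAU	UAU	1	H	Y	87
ndhB	94034	-	ACG	AUG	2	T	M	83
ndhB	94427	-	UCA	UUA	2	S	L	96
ndhD	112418	-	UCA	UUA	2	S	L	77
ndhD	112622	-	UCA	UUA	2	S	L	95
ndhD	112913	-	ACA	AUA	2	T	I	97
ndhD	113294	-	ACG	AUG	2	T	M	14
ndhE	114034	-	CCG	CUG	2	P	L	86
ndhA	115872	-	UCU	UUU	2	S	F	84
ndhA	117875	-	UCA	UUA	2	S	L	93
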