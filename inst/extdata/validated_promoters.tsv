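target_id	minus35	spacer	minus10	distance_bp	validated	promoter_class
sco2334	AACG	TTTCCGTTCGAATTAT	CGTCT	54	TRUE	II
sco2611-2609	AACG	GATCCCACCGTTGGCC	CGTCT	157	TRUE	III
sco2897	AACG	GAACCCGCGGTGCGAG	AGTCT	260	TRUE	II
sco3044	GACC	TGAGGGGCCCCGCACG	CGTCT	335	TRUE	II
sco3194	AACC	CCACGGGCCGCCGGGCA	CCTCT	46	TRUE	III
hrdD	AACC	CTCAGGCGGTACGGGC	CGTCT	375	TRUE	III
sco3396	AACC	TCGCCCGACATTTCCT	CATCT	151	TRUE	I
sco3397	AACC	TCTCCCTCCGAGACAC	CGTCC	95	TRUE	I
sco3712	ATCC	CGCGGCGGGTTTCTCC	CGTCC	5	TRUE	II
sco4134	AACC	CGCGCCCCCACACCCC	CGTCT	33	TRUE	II
sco4263	CACC	GTTCACCGCAGTCGTT	CGTCT	38	TRUE	I
sco4471	AACC	CGCTCGTTCGTCGCGT	CCTCT	38	TRUE	II
sco4847	AACC	CGATGACCCCGACGAC	CGTCC	271	TRUE	II
sco4934	AACC	GCCGCCCGGGGTTTCGT	CGTCT	172	TRUE	III
sco5030	AACC	TCGCGCAGCCCCTCAC	CGTCT	94	TRUE	II
sco5358	AACC	CTGTCCCGAGTTCCGC	CGTCT	108	TRUE	II
sco6179-6190	AACC	TGGTCCCCGTTTTCGT	CGTCT	147	TRUE	II
sco7233	AACC	CGAAGGATCTCCATCC	CCTCC	69	TRUE	I
sco7657-7658	AACC	GGGCATCCGAGCGCTC	CCTCT	75	TRUE	I
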