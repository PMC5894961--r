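# synthetic example capture panel (not real genome coordinates)
chr1	11000	11150	CACNA2D4_exon1
chr1	12150	12300	CACNA2D4_exon2
chr1	13300	13450	CACNA2D4_exon3
chr1	14450	14600	CACNA2D4_exon4
chr1	15600	15750	CACNA2D4_exon5
chr1	16750	16900	CACNA2D4_exon6
chr1	17900	18050	CACNA2D4_exon7
chr1	19050	19200	CACNA2D4_exon8
chr1	20200	20350	CACNA2D4_exon9
chr1	21350	21500	CACNA2D4_exon10
chr1	22500	22650	CACNA2D4_exon11
chr1	23650	23800	CACNA2D4_exon12
chr1	24800	24950	CACNA2D4_exon13
chr1	25950	26100	CACNA2D4_exon14
chr1	27100	27250	CACNA2D4_exon15
chr1	28250	28400	CACNA2D4_exon16
chr1	29400	29550	CACNA2D4_exon17
chr1	30550	30700	CACNA2D4_exon18
chr1	31700	31850	CACNA2D4_exon19
chr1	32850	33000	CACNA2D4_exon20
chr1	34000	34150	CACNA2D4_exon21
chr1	35150	35300	CACNA2D4_exon22
chr1	36300	36450	CACNA2D4_exon23
chr1	37450	37600	CACNA2D4_exon24
chr1	38600	38750	CACNA2D4_exon25
chr1	39750	39900	CACNA2D4_exon26
chr2	11000	11150	CRX_exon1
chr2	12150	12300	CRX_exon2
chr2	13300	13450	CRX_exon3
chr2	14450	14600	CRX_exon4
chr3	11000	11150	TULP1_exon1
chr3	12150	12300	TULP1_exon2
chr3	13300	13450	TULP1_exon3
chr3	14450	14600	TULP1_exon4
chr3	15600	15750	TULP1_exon5
chr3	16750	16900	TULP1_exon6
chr3	17900	18050	TULP1_exon7
chr3	19050	19200	TULP1_exon8
chr3	20200	20350	TULP1_exon9
chr3	21350	21500	TULP1_exon10
chr3	22500	22650	TULP1_exon11
chr3	23650	23800	TULP1_exon12
chr3	24800	24950	TULP1_exon13
chr3	25950	26100	TULP1_exon14
chr3	27100	27250	TULP1_exon15
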