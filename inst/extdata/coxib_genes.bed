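chr20	44637547	44645200	MMP9
chr16	75262928	75301951	BCAR1
chr6	43737946	43754224	VEGFA
chr1	181452685	181775921	CACNA1E
chr17	168231409	168377250	PTGS1
chr5	48612848	48704623	PTGS2
chr1	41997125	42027975	CA1
chr10	160723649	160779493	CA2
chr4	92476994	92483900	CA4
chr18	25460692	25641339	CA5A
chr17	185624118	185665195	CA6
chr15	125091065	125174511	CA7
chr7	43580007	43662310	CA9
chr4	34841184	34998034	CA12
chr5	62866086	62948818	CA13
chr14	82995884	83224484	CA14
chr20	111923851	112156936	PDPK1
chr18	199383368	199397313	AKT1
chr15	100241506	100416395	CCND1
chr3	183190095	183311030	CDKN1A
chr9	91500827	91627896	EGFR
chr4	89376283	89463809	ESR1
chr5	6322647	6442162	GSK3B
chr13	125806033	125895426	HIF1A
chr5	22296749	22484208	IL6
chr20	154550996	154629991	MAPK1
chr2	7517734	7722823	MMP2
chr8	154717137	154729497	NFKB1
chr3	6921548	7040011	NOS2
chr1	190950239	191185736	PLA2G4A
chr10	48159029	48193048	PPARG
chr11	139110236	139275296	PTEN
chr15	190855339	190957632	RELA
chr22	198704056	198791611	SLC29A1
chr8	123985085	124098211	TNF
chr4	28979768	29185370	TP53
chr4	164157103	164282607	TYMS
chr22	39214940	39439705	ABCB1
chr18	63300069	63363574	ABCG2
chr13	101668556	101684804	ALOX5
chr5	115149252	115217262	CYP2C9
chr4	198710134	198834443	CYP3A4
chr2	194982937	195196698	DNMT1
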